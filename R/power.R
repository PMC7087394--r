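# Analytic power for GRS-instrumented MR replication designs.
#
# The asymptotic test statistic of a two-stage least-squares estimate with
# an instrument explaining a fraction r2 of the exposure variance has
# noncentrality sqrt(n * r2) * beta (effects in SD-outcome per SD-exposure).
# For a binary outcome on the log-odds scale the effective sample size is
# scaled by the case-control variance factor p(1-p).

power_result <- function(...) structure(list(...), class = "power_result")

#' @export
print.power_result <- function(x, ...) {
  unit <- if (isTRUE(x$binary)) "log-odds" else "SD"
  cat(sprintf("Power: n = %d, R2 = %.3f, alpha = %.3f, power = %.2f -> MDE = %.4f %s",
              x$n, x$r2_xz, x$alpha, x$power, x$mde, unit))
  if (isTRUE(x$binary))
    cat(sprintf(" (OR %.2f, case fraction %.2f)", exp(x$mde), x$case_fraction))
  cat("\n")
  invisible(x)
}

check_power_args <- function(n, r2_xz, alpha, power) {
  if (!is.numeric(n) || length(n) != 1 || n < 10)
    abort_input("`n` must be a single number >= 10")
  assert_scalar_number(r2_xz, "r2_xz", 0, 1, strict = TRUE)
  assert_scalar_number(alpha, "alpha", 0, 1, strict = TRUE)
  assert_scalar_number(power, "power", 0, 1, strict = TRUE)
}

#' Minimal detectable effect for a continuous outcome
#'
#' \deqn{MDE = (z_{1-\alpha/2} + z_{power}) / \sqrt{n \cdot R^2_{XZ}},}
#' in SD of the outcome per SD of the exposure, for a two-sided test.
#'
#' @param n Outcome sample size (>= 10).
#' @param r2_xz Fraction of exposure variance explained by the instrument.
#' @param alpha Two-sided type-I error rate; default 0.05.
#' @param power Target power; default 0.80.
#' @return A \code{power_result} with field \code{mde}.
#' @examples
#' mde_continuous(4566, 0.05)$mde  # ~0.185
#' @export
mde_continuous <- function(n, r2_xz, alpha = 0.05, power = 0.80) {
  check_power_args(n, r2_xz, alpha, power)
  mde <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
    sqrt(n * r2_xz)
  power_result(n = as.integer(n), r2_xz = r2_xz, alpha = alpha,
               power = power, mde = mde, binary = FALSE,
               case_fraction = NA_real_)
}

#' Minimal detectable effect for a binary outcome (log-odds scale)
#'
#' \deqn{MDE = (z_{1-\alpha/2} + z_{power}) /
#'       \sqrt{n \cdot R^2_{XZ} \cdot p (1 - p)},}
#' where \eqn{p} is the case fraction; also reported as an odds ratio.
#'
#' @inheritParams mde_continuous
#' @param case_fraction Fraction of cases in the outcome sample, in (0, 1).
#' @return A \code{power_result} with fields \code{mde} (log-odds) and
#'   \code{odds_ratio}.
#' @export
mde_binary <- function(n, r2_xz, case_fraction, alpha = 0.05, power = 0.80) {
  check_power_args(n, r2_xz, alpha, power)
  assert_scalar_number(case_fraction, "case_fraction", 0, 1, strict = TRUE)
  mde <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
    sqrt(n * r2_xz * case_fraction * (1 - case_fraction))
  res <- power_result(n = as.integer(n), r2_xz = r2_xz, alpha = alpha,
                      power = power, mde = mde, binary = TRUE,
                      case_fraction = case_fraction)
  res$odds_ratio <- exp(mde)
  res
}

#' Achieved power at a given true effect
#'
#' \deqn{Power = \Phi(\sqrt{n \cdot R^2_{XZ}} \cdot |\beta| -
#'       z_{1-\alpha/2}),} the inverse of \code{\link{mde_continuous}}:
#' plugging in the MDE returns the target power exactly.
#'
#' @inheritParams mde_continuous
#' @param effect True effect size (> 0; SD outcome per SD exposure).
#' @return Achieved power (scalar). At \code{effect = 0} this equals
#'   \code{alpha/2}, the one-tail rejection rate under the null.
#' @export
power_at_effect <- function(n, r2_xz, effect, alpha = 0.05) {
  check_power_args(n, r2_xz, alpha, 0.5)
  if (!is.numeric(effect) || length(effect) != 1 || effect < 0)
    abort_input("`effect` must be a single number >= 0")
  stats::pnorm(sqrt(n * r2_xz) * effect - stats::qnorm(1 - alpha / 2))
}

#' Power table for a set of replication designs
#'
#' @param designs data.frame with columns \code{cohort, n, r2} and
#'   optionally \code{case_fraction} (NA = continuous outcome).
#' @param alpha,power As in \code{\link{mde_continuous}}.
#' @return data.frame with columns \code{cohort, n, r2, alpha, power, mde,
#'   odds_ratio}.
#' @export
power_table <- function(designs, alpha = 0.05, power = 0.80) {
  rows <- lapply(seq_len(nrow(designs)), function(i) {
    cf <- if ("case_fraction" %in% names(designs)) designs$case_fraction[i]
          else NA_real_
    r <- if (is.na(cf))
      mde_continuous(designs$n[i], designs$r2[i], alpha, power)
    else
      mde_binary(designs$n[i], designs$r2[i], cf, alpha, power)
    data.frame(cohort = designs$cohort[i], n = r$n, r2 = r$r2_xz,
               alpha = alpha, power = power, mde = r$mde,
               odds_ratio = if (isTRUE(r$binary)) r$odds_ratio else NA_real_)
  })
  do.call(rbind, rows)
}
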