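new_mr_estimate <- function(method, beta, se, n_snps, df = Inf, extras = list()) {
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  pval <- if (is.finite(df)) 2 * stats::pt(-abs(beta / se), df)
          else 2 * stats::pnorm(-abs(beta / se))
  structure(c(list(method = method, beta = beta, se = se,
                   ci_low = beta - crit * se, ci_high = beta + crit * se,
                   pval = pval, n_snps = n_snps), extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s]: beta = %.4f (se %.4f, 95%% CI %.4f to %.4f), p = %.3g, %d SNPs\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4f (se %.4f, p = %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_p))
  if (!is.null(x$Q))
    cat(sprintf("  Q = %.2f (p = %.3g), I2 = %.1f%%, tau2 = %.4g\n",
                x$Q, x$Q_p, 100 * x$I2, x$tau2 %||% 0))
  invisible(x)
}

#' Flip an estimate to the per-unit-decrease reporting orientation
#'
#' Estimators return effects per unit increase of the exposure; published
#' forest plots for menarche timing report per year decrease. This flips
#' the sign of the causal slope (and Egger intercept) and swaps the CI.
#'
#' @param est An \code{mr_estimate}.
#' @return The reoriented \code{mr_estimate}.
#' @export
flip_orientation <- function(est) {
  est$beta <- -est$beta
  ci <- c(-est$ci_high, -est$ci_low)
  est$ci_low <- ci[1]; est$ci_high <- ci[2]
  if (!is.null(est$intercept)) est$intercept <- -est$intercept
  est$orientation <- "per unit decrease"
  est
}

complement_allele <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

#' Harmonize exposure and outcome summary statistics
#'
#' Restricts to the shared rsids and aligns every outcome row to the
#' exposure's effect allele: straight matches pass through; swapped
#' effect/other alleles flip the outcome beta (and eaf); strand mismatches
#' are resolved by complementing the outcome alleles first. Palindromic
#' variants (A/T or C/G) whose minor-allele frequency is within
#' \code{palindrome_eaf_window} of 0.5 are ambiguous and dropped; otherwise
#' they are oriented by comparing allele frequencies. Rows that cannot be
#' reconciled are dropped with a reason.
#'
#' @param exposure_stats A \code{variant_panel} (or data.frame with rsid,
#'   effect_allele, other_allele, eaf, beta_exposure, se_exposure).
#' @param outcome_stats A \code{summary_stats} table (rsid, effect_allele,
#'   other_allele, eaf, beta_outcome, se_outcome).
#' @param palindrome_eaf_window Half-width of the ambiguous frequency zone
#'   around 0.5; default 0.08.
#' @return data.frame of class \code{mr_input} with columns \code{rsid,
#'   beta_exp, se_exp, beta_out, se_out, palindromic, flipped}; dropped rows
#'   are recorded in attribute \code{"dropped"}.
#' @export
harmonize <- function(exposure_stats, outcome_stats,
                      palindrome_eaf_window = 0.08) {
  shared <- intersect(exposure_stats$rsid, outcome_stats$rsid)
  if (length(shared) == 0)
    abort_input("no shared rsids between exposure and outcome statistics")
  ex <- exposure_stats[match(shared, exposure_stats$rsid), ]
  ou <- outcome_stats[match(shared, outcome_stats$rsid), ]

  pal <- ex$effect_allele == complement_allele(ex$other_allele)
  keep <- rep(TRUE, length(shared))
  flip <- rep(FALSE, length(shared))
  reason <- rep("", length(shared))

  for (i in seq_along(shared)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    oe <- ou$effect_allele[i]; oo <- ou$other_allele[i]
    if (pal[i]) {
      maf <- pmin(ou$eaf[i], 1 - ou$eaf[i])
      if (is.na(maf) || maf > 0.5 - palindrome_eaf_window) {
        keep[i] <- FALSE; reason[i] <- "ambiguous palindromic variant"
      } else {
        # orient by frequency: outcome eaf near exposure eaf => same allele
        flip[i] <- abs(ou$eaf[i] - ex$eaf[i]) > abs((1 - ou$eaf[i]) - ex$eaf[i])
      }
    } else if (oe == ea && oo == oa) {
      # aligned
    } else if (oe == oa && oo == ea) {
      flip[i] <- TRUE
    } else if (complement_allele(oe) == ea && complement_allele(oo) == oa) {
      # opposite strand, aligned
    } else if (complement_allele(oe) == oa && complement_allele(oo) == ea) {
      flip[i] <- TRUE
    } else {
      keep[i] <- FALSE; reason[i] <- "allele mismatch"
    }
  }

  out <- data.frame(
    rsid = shared,
    beta_exp = ex$beta_exposure, se_exp = ex$se_exposure,
    beta_out = ifelse(flip, -ou$beta_outcome, ou$beta_outcome),
    se_out = ou$se_outcome,
    palindromic = pal, flipped = flip, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(rsid = shared[!keep],
                                     reason = reason[!keep])
  class(out) <- c("mr_input", "data.frame")
  out
}

#' Per-variant Wald ratios
#'
#' \eqn{r_j = \beta_{out,j} / \beta_{exp,j}} with first-order delta-method
#' standard error \eqn{|se_{out,j} / \beta_{exp,j}|} (exposure uncertainty
#' ignored, appropriate for strong instruments). A second-order version
#' adding the exposure term
#' \eqn{\sqrt{se_{out}^2/\beta_{exp}^2 + \beta_{out}^2 se_{exp}^2/\beta_{exp}^4}}
#' is available via \code{order = 2}. Variants with
#' \eqn{\beta_{exp} = 0} are excluded with a warning.
#'
#' @param mr_input An \code{mr_input} table.
#' @param order 1 (default) or 2.
#' @return data.frame with \code{rsid, ratio, se}.
#' @export
wald_ratios <- function(mr_input, order = 1) {
  zero <- mr_input$beta_exp == 0
  if (any(zero)) {
    warning(sprintf("%d variant(s) with zero exposure effect excluded",
                    sum(zero)))
    mr_input <- mr_input[!zero, , drop = FALSE]
  }
  ratio <- mr_input$beta_out / mr_input$beta_exp
  se <- if (order == 1) abs(mr_input$se_out / mr_input$beta_exp) else
    sqrt(mr_input$se_out^2 / mr_input$beta_exp^2 +
           mr_input$beta_out^2 * mr_input$se_exp^2 / mr_input$beta_exp^4)
  data.frame(rsid = mr_input$rsid, ratio = ratio, se = se,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools the per-variant Wald ratios by inverse-variance weighting.
#' Fixed effects: \eqn{\hat\beta = \sum w_j r_j / \sum w_j}, \eqn{w_j =
#' 1/se_j^2}, \eqn{se = 1/\sqrt{\sum w_j}}. Heterogeneity: Cochran's
#' \eqn{Q = \sum w_j (r_j - \hat\beta)^2} and \eqn{I^2 = \max(0, (Q -
#' df)/Q)}. Random effects uses the DerSimonian-Laird moment estimator
#' \eqn{\tau^2 = \max(0, (Q - df)/(\sum w - \sum w^2/\sum w))} and weights
#' \eqn{1/(se_j^2 + \tau^2)} (equivalent to a random-effects meta-analysis
#' of the ratios). With a single variant, random effects falls back to
#' fixed with a warning.
#'
#' @param mr_input An \code{mr_input} table.
#' @param model "random" (default) or "fixed".
#' @return An \code{mr_estimate} with extras \code{tau2, Q, Q_p, I2}.
#' @export
mr_ivw <- function(mr_input, model = c("random", "fixed")) {
  model <- match.arg(model)
  wr <- wald_ratios(mr_input)
  k <- nrow(wr)
  if (k < 1) abort_input("IVW needs at least one variant")
  w <- 1 / wr$se^2
  beta_f <- sum(w * wr$ratio) / sum(w)
  Q <- sum(w * (wr$ratio - beta_f)^2)
  df <- k - 1
  I2 <- if (Q > 0 && df > 0) max(0, (Q - df) / Q) else 0
  Q_p <- if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_
  if (model == "random" && k < 2) {
    warning("random-effects IVW needs >= 2 variants; falling back to fixed")
    model <- "fixed"
  }
  if (model == "fixed") {
    return(new_mr_estimate("ivw_fixed", beta_f, sqrt(1 / sum(w)), k,
                           extras = list(tau2 = 0, Q = Q, Q_p = Q_p, I2 = I2)))
  }
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr2 <- 1 / (wr$se^2 + tau2)
  beta_r <- sum(wr2 * wr$ratio) / sum(wr2)
  new_mr_estimate("ivw_random", beta_r, sqrt(1 / sum(wr2)), k,
                  extras = list(tau2 = tau2, Q = Q, Q_p = Q_p, I2 = I2))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an unconstrained intercept, weights \eqn{1/se_{out}^2}, after
#' orienting every variant so \eqn{\beta_{exp} \ge 0}. The slope is the
#' causal estimate (consistent under InSIDE even with directional
#' pleiotropy); a non-zero intercept indicates unbalanced horizontal
#' pleiotropy. Standard errors use a multiplicative overdispersion scale
#' floored at 1, with two-sided p-values from the t distribution on
#' \eqn{k - 2} degrees of freedom.
#'
#' @param mr_input An \code{mr_input} with >= 3 variants.
#' @return An \code{mr_estimate} with extras \code{intercept, intercept_se,
#'   intercept_p, scale, Q, Q_p, I2}.
#' @export
mr_egger <- function(mr_input) {
  k <- nrow(mr_input)
  if (k < 3)
    abort_input("MR-Egger needs at least 3 variants",
                class = "mrphewas_method_error")
  sgn <- ifelse(mr_input$beta_exp < 0, -1, 1)
  x <- mr_input$beta_exp * sgn
  y <- mr_input$beta_out * sgn
  w <- 1 / mr_input$se_out^2
  X <- cbind(1, x)
  A <- crossprod(X, w * X)
  b <- drop(solve(A, crossprod(X, w * y)))
  resid <- y - drop(X %*% b)
  rss <- sum(w * resid^2)
  scale <- max(1, rss / (k - 2))
  covb <- scale * solve(A)
  slope_se <- sqrt(covb[2, 2])
  int_se <- sqrt(covb[1, 1])
  df <- k - 2
  Q <- rss
  new_mr_estimate("egger", unname(b[2]), slope_se, k, df = df,
                  extras = list(
                    intercept = unname(b[1]),
                    intercept_se = int_se,
                    intercept_p = 2 * stats::pt(-abs(b[1] / int_se), df),
                    scale = scale, Q = Q,
                    Q_p = stats::pchisq(Q, df, lower.tail = FALSE),
                    I2 = if (Q > 0) max(0, (Q - df) / Q) else 0))
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; ws <- w[ord] / sum(w)
  cum <- cumsum(ws) - ws / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  stats::approx(cum, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR estimate
#'
#' Orders the per-variant ratio estimates and takes the value at cumulative
#' normalized inverse-variance weight 0.5 (linear interpolation between
#' adjacent ratios). Consistent when valid instruments carry more than half
#' of the total weight. The standard error comes from a parametric
#' bootstrap: exposure and outcome effects are redrawn from
#' \eqn{N(\hat\beta, se^2)} per variant and the estimator recomputed.
#'
#' @param mr_input An \code{mr_input} with >= 3 variants.
#' @param bootstrap_reps Bootstrap replicates; default 1000.
#' @param seed Integer seed for the bootstrap.
#' @return An \code{mr_estimate} with extra \code{bootstrap_reps}.
#' @export
mr_weighted_median <- function(mr_input, bootstrap_reps = 1000, seed = 1) {
  k <- nrow(mr_input)
  if (k < 3) abort_input("weighted median needs at least 3 variants",
                         class = "mrphewas_method_error")
  wr <- wald_ratios(mr_input)
  w <- 1 / wr$se^2
  if (all(w == 0)) abort_input("all weights are zero")
  est <- weighted_median_point(wr$ratio, w)
  se <- bootstrap_summary_se(mr_input, bootstrap_reps, seed, function(bi) {
    bwr <- wald_ratios(bi)
    weighted_median_point(bwr$ratio, 1 / bwr$se^2)
  })
  new_mr_estimate("weighted_median", est, se, k,
                  extras = list(bootstrap_reps = bootstrap_reps))
}

# parametric bootstrap over summary statistics
bootstrap_summary_se <- function(mr_input, reps, seed, fn) {
  set.seed(substream_seed(seed, "summary-bootstrap"))
  vals <- vapply(seq_len(reps), function(b) {
    bi <- mr_input
    bi$beta_exp <- stats::rnorm(nrow(bi), mr_input$beta_exp, mr_input$se_exp)
    bi$beta_out <- stats::rnorm(nrow(bi), mr_input$beta_out, mr_input$se_out)
    bi$beta_exp[bi$beta_exp == 0] <- 1e-12
    fn(bi)
  }, numeric(1))
  stats::sd(vals)
}

mode_point <- function(ratio, w = NULL, phi = 1, grid_n = 10000) {
  if (length(unique(ratio)) == 1) return(ratio[1])
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) * length(ratio)^(-1 / 5)
  if (s == 0) s <- 0.9 * stats::sd(ratio) * length(ratio)^(-1 / 5)
  h <- phi * s
  if (h <= 0 || !is.finite(h)) return(stats::median(ratio))
  lo <- min(ratio) - 3 * h; hi <- max(ratio) + 3 * h
  dn <- stats::density(ratio, bw = h, kernel = "gaussian",
                       weights = if (is.null(w)) NULL else w / sum(w),
                       from = lo, to = hi, n = grid_n)
  dn$x[which.max(dn$y)]
}

#' Mode-based MR estimate (simple or weighted)
#'
#' Smooths the per-variant ratio estimates with a normal kernel whose
#' bandwidth is \code{phi} times the modified-Silverman scale
#' \eqn{0.9 \min(sd, mad) k^{-1/5}}, and takes the density argmax on a grid
#' spanning the ratios plus three bandwidths. The weighted variant gives
#' each ratio a normalized inverse-variance kernel weight. Consistent when
#' the largest homogeneous cluster of instruments is valid (zero modal
#' pleiotropy). If all ratios coincide, that common value is returned with
#' zero standard error.
#'
#' @param mr_input An \code{mr_input} with >= 3 variants.
#' @param weighted Use inverse-variance kernel weights? Default FALSE.
#' @param phi Bandwidth multiplier; default 1.
#' @param bootstrap_reps Parametric bootstrap replicates; default 1000.
#' @param seed Integer seed.
#' @param grid_n Density grid size; default 10000.
#' @return An \code{mr_estimate} with extra \code{bootstrap_reps}.
#' @export
mr_mode <- function(mr_input, weighted = FALSE, phi = 1,
                    bootstrap_reps = 1000, seed = 1, grid_n = 10000) {
  k <- nrow(mr_input)
  if (k < 3) abort_input("mode estimator needs at least 3 variants",
                         class = "mrphewas_method_error")
  wr <- wald_ratios(mr_input)
  w <- if (weighted) 1 / wr$se^2 else NULL
  if (length(unique(wr$ratio)) == 1) {
    return(new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                           wr$ratio[1], 0, k,
                           extras = list(bootstrap_reps = 0L)))
  }
  est <- mode_point(wr$ratio, w, phi, grid_n)
  se <- bootstrap_summary_se(mr_input, bootstrap_reps, seed, function(bi) {
    bwr <- wald_ratios(bi)
    mode_point(bwr$ratio, if (weighted) 1 / bwr$se^2 else NULL, phi,
               grid_n = min(grid_n, 2048))
  })
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  est, se, k, extras = list(bootstrap_reps = bootstrap_reps))
}

#' Cross-cohort heterogeneity of causal estimates
#'
#' Cochran's Q across independent estimates with fixed-effect weights
#' \eqn{1/se^2}, \eqn{I^2 = \max(0, (Q - df)/Q)} and the chi-square tail
#' p-value on \eqn{k - 1} degrees of freedom.
#'
#' @param estimates List of \code{mr_estimate} objects (or a data.frame
#'   with \code{beta} and \code{se}).
#' @return List with \code{Q, df, p, I2}.
#' @export
cohort_heterogeneity <- function(estimates) {
  if (is.data.frame(estimates)) {
    beta <- estimates$beta; se <- estimates$se
  } else {
    beta <- vapply(estimates, `[[`, numeric(1), "beta")
    se <- vapply(estimates, `[[`, numeric(1), "se")
  }
  if (length(beta) < 2) abort_input("need at least 2 estimates")
  w <- 1 / se^2
  mu <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - mu)^2)
  df <- length(beta) - 1
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = if (Q > 0) max(0, (Q - df) / Q) else 0)
}
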