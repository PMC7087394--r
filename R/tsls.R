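# One-sample (two-stage) and multivariable MR on individual-level data.

fit_stage <- function(X, y, binary) {
  if (binary) {
    g <- stats::glm.fit(X, y, family = stats::binomial())
    g$coefficients
  } else {
    stats::lm.fit(X, y)$coefficients
  }
}

#' One-sample Mendelian randomization (two-stage regression)
#'
#' Stage 1 regresses the exposure on the instrument score (plus covariates)
#' by linear regression; stage 2 regresses the outcome on the genetically
#' predicted exposure (plus covariates) -- logistic when the outcome is
#' 0/1, linear otherwise. Standard errors come from a nonparametric
#' bootstrap over individuals in which both stages are re-run, which
#' propagates the first-stage uncertainty that a naive second-stage SE
#' ignores. A weak first stage (partial F below \code{f_floor}) flags the
#' estimate rather than failing.
#'
#' @param cohort An \code{mr_cohort}.
#' @param score Per-individual instrument score.
#' @param outcome Outcome name (phenome or built-in) or numeric vector;
#'   binary outcomes must be coded 0/1.
#' @param covariates Optional covariate matrix.
#' @param bootstrap_reps Bootstrap replicates; default 1000.
#' @param seed Integer seed.
#' @param f_floor Weak-instrument warning floor for the stage-1 partial F;
#'   default 10.
#' @return An \code{mr_estimate} (method "tsls") with extras
#'   \code{stage1_f}, \code{weak_instrument}, \code{bootstrap_reps},
#'   \code{binary}. The effect is per unit increase of the exposure; use
#'   \code{\link{flip_orientation}} for the per-year-decrease convention.
#' @export
one_sample_mr <- function(cohort, score, outcome, covariates = NULL,
                          bootstrap_reps = 1000, seed = 1, f_floor = 10) {
  y <- resolve_trait(cohort, outcome)
  x <- cohort$exposure
  keep <- !is.na(y) & !is.na(score) & !is.na(x)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
    cv <- covariates[keep, , drop = FALSE]
  } else cv <- NULL
  y <- y[keep]; x <- x[keep]; s <- score[keep]
  n <- length(y)
  if (stats::var(s) == 0) abort_input("the score is constant")
  binary <- all(y %in% c(0, 1))

  two_stage <- function(idx) {
    X1 <- cbind(1, s[idx], cv[idx, , drop = FALSE])
    b1 <- stats::lm.fit(X1, x[idx])$coefficients
    xhat <- drop(X1 %*% b1)
    X2 <- cbind(1, xhat, cv[idx, , drop = FALSE])
    unname(fit_stage(X2, y[idx], binary)[2])
  }

  beta <- two_stage(seq_len(n))
  strength <- instrument_strength(s, x, cv)
  set.seed(substream_seed(seed, "tsls-bootstrap"))
  boot <- vapply(seq_len(bootstrap_reps), function(b)
    two_stage(sample.int(n, n, replace = TRUE)), numeric(1))
  se <- stats::sd(boot)
  est <- new_mr_estimate("tsls", beta, se, n_snps = NA_integer_,
                         extras = list(stage1_f = strength$f_statistic,
                                       weak_instrument = strength$f_statistic < f_floor,
                                       bootstrap_reps = bootstrap_reps,
                                       binary = binary, n = n))
  if (est$weak_instrument)
    warning(sprintf("weak instrument: stage-1 F = %.1f < %g",
                    strength$f_statistic, f_floor))
  est
}

#' Multivariable Mendelian randomization
#'
#' Joint two-stage regression for several instrumented exposures: stage 1
#' regresses each exposure on all instrument scores together (plus
#' covariates); stage 2 regresses the outcome on all predicted exposures,
#' giving the direct effect of each exposure holding the others fixed --
#' the instrumental-variable analogue of mutually adjusted multivariable
#' regression. Used to separate exposure effects from mediation through
#' adult BMI (or height for lung traits). Bootstrap over individuals
#' re-runs both stages.
#'
#' @param cohort An \code{mr_cohort}.
#' @param scores Named list (exposure name -> per-individual score); >= 2
#'   entries, names resolvable as cohort traits.
#' @param outcome Outcome name or numeric vector (0/1 outcomes use logistic
#'   stage 2).
#' @param covariates Optional covariate matrix.
#' @param bootstrap_reps Bootstrap replicates; default 1000.
#' @param seed Integer seed.
#' @param cor_limit Absolute score correlation above which the pair is
#'   declared collinear; default 0.999.
#' @return Named list of \code{mr_estimate} (method "mvmr"), one per
#'   exposure.
#' @export
multivariable_mr <- function(cohort, scores, outcome, covariates = NULL,
                             bootstrap_reps = 1000, seed = 1,
                             cor_limit = 0.999) {
  if (length(scores) < 2) abort_input("multivariable MR needs >= 2 scores")
  if (is.null(names(scores)) || any(names(scores) == ""))
    abort_input("`scores` must be a named list (exposure name -> score)")
  S <- do.call(cbind, scores)
  cm <- stats::cor(S)
  cm[upper.tri(cm, diag = TRUE)] <- 0
  worst <- which(abs(cm) > cor_limit, arr.ind = TRUE)
  if (nrow(worst))
    abort_input(sprintf("collinear scores: '%s' and '%s' (|r| > %g)",
                        names(scores)[worst[1, 2]], names(scores)[worst[1, 1]],
                        cor_limit),
                class = "mrphewas_estimation_error")
  exposures <- lapply(names(scores), function(e) resolve_trait(cohort, e))
  names(exposures) <- names(scores)
  y <- resolve_trait(cohort, outcome)
  keep <- !is.na(y) & stats::complete.cases(S) &
    Reduce(`&`, lapply(exposures, function(e) !is.na(e)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
    cv <- covariates[keep, , drop = FALSE]
  } else cv <- NULL
  y <- y[keep]; S <- S[keep, , drop = FALSE]
  E <- vapply(exposures, function(e) e[keep], numeric(sum(keep)))
  n <- length(y)
  binary <- all(y %in% c(0, 1))
  K <- ncol(S)

  two_stage <- function(idx) {
    X1 <- cbind(1, S[idx, , drop = FALSE], cv[idx, , drop = FALSE])
    b1 <- stats::lm.fit(X1, E[idx, , drop = FALSE])$coefficients
    Ehat <- X1 %*% b1
    X2 <- cbind(1, Ehat, cv[idx, , drop = FALSE])
    unname(fit_stage(X2, y[idx], binary)[seq_len(K) + 1])
  }

  beta <- two_stage(seq_len(n))
  set.seed(substream_seed(seed, "mvmr-bootstrap"))
  boot <- t(vapply(seq_len(bootstrap_reps), function(b)
    two_stage(sample.int(n, n, replace = TRUE)), numeric(K)))
  se <- apply(boot, 2, stats::sd)
  out <- lapply(seq_len(K), function(j)
    new_mr_estimate("mvmr", beta[j], se[j], n_snps = NA_integer_,
                    extras = list(exposure = names(scores)[j],
                                  bootstrap_reps = bootstrap_reps,
                                  binary = binary, n = n)))
  stats::setNames(out, names(scores))
}
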