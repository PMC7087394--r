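#' Infer the analysis type of a phenome trait
#'
#' Rule set mirroring automated phenome-scan tools: a declared kind always
#' wins; otherwise exactly two distinct non-missing values is binary;
#' numeric integer codes with at most \code{max_ordered_levels} distinct
#' values are treated as ordered categorical; non-numeric codes are
#' unordered categorical; anything else is continuous.
#'
#' @param values Trait vector.
#' @param declared Optional declared kind (wins if supplied).
#' @param max_ordered_levels Distinct-value cutoff separating ordered
#'   categorical from continuous integer codes; default 20.
#' @return One of "continuous", "binary", "ordered", "unordered", or
#'   "constant" when there is no variation.
#' @export
infer_trait_type <- function(values, declared = NULL,
                             max_ordered_levels = 20) {
  if (!is.null(declared))
    return(match.arg(declared, c("continuous", "binary", "ordered",
                                 "unordered")))
  v <- values[!is.na(values)]
  u <- unique(v)
  if (length(u) < 2) return("constant")
  if (length(u) == 2) return("binary")
  if (!is.numeric(v)) return("unordered")
  if (all(v == round(v)) && length(u) <= max_ordered_levels) return("ordered")
  "continuous"
}

#' Rank-based inverse normal transformation
#'
#' Maps average ranks through the standard-normal quantile function at
#' \code{(rank - offset) / (n + 1 - 2*offset)}; the default offset 3/8 is
#' the Blom constant, giving \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}. Ties get
#' equal transformed values; missing values are preserved.
#'
#' @param values Numeric vector (>= 2 non-missing values).
#' @param offset Rank offset constant; default 3/8.
#' @return Transformed vector, same length and NA pattern as the input.
#' @examples
#' inverse_normal_transform(c(3, 1, 2))
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) abort_input("need at least 2 non-missing values to transform")
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - offset) / (n + 1 - 2 * offset))
  out
}

#' Options controlling the phenome scan
#'
#' @param min_cases Minimum case count for binary traits; below it the trait
#'   is skipped. Default 50.
#' @param max_ordered_levels Distinct-value cutoff for the continuous vs
#'   ordered rule. Default 20.
#' @param int_offset Rank offset of the inverse normal transform. Default 3/8.
#' @param fdr_q Target false discovery rate. Default 0.05.
#' @param alpha Family-wise alpha for the Bonferroni threshold. Default 0.05.
#' @return List of class \code{scan_options}.
#' @export
scan_options <- function(min_cases = 50, max_ordered_levels = 20,
                         int_offset = 3 / 8, fdr_q = 0.05, alpha = 0.05) {
  structure(list(min_cases = min_cases,
                 max_ordered_levels = max_ordered_levels,
                 int_offset = int_offset, fdr_q = fdr_q, alpha = alpha),
            class = "scan_options")
}

scan_result_row <- function(trait, test = NA_character_, n = NA_integer_,
                            beta = NA_real_, se = NA_real_, pval = NA_real_,
                            category = "", skip_reason = "") {
  data.frame(trait = trait, category = category, test = test,
             n = as.integer(n), beta = unname(beta), se = unname(se),
             pval = unname(pval), skip_reason = skip_reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test one trait against the score
#'
#' Dispatches by trait kind with the score as the exposure term:
#' continuous traits are inverse-normal transformed then fit by linear
#' regression; binary traits by logistic regression; ordered categorical by
#' proportional-odds logistic regression (\code{MASS::polr}); unordered
#' categorical by multinomial logistic regression (\code{nnet::multinom})
#' with the most frequent level as reference, reporting only the likelihood-
#' ratio p-value of the score term on \eqn{L - 1} degrees of freedom.
#' Two-sided p-values for the single-coefficient tests use the large-sample
#' normal. Non-convergence or separation yields a flagged row with the
#' reason and no p-value; binary traits with fewer cases (or controls) than
#' \code{opts$min_cases} are skipped.
#'
#' @param score Per-individual instrument score.
#' @param values Trait vector.
#' @param kind Trait kind from \code{\link{infer_trait_type}}; NULL infers.
#' @param covariates Optional covariate matrix.
#' @param trait Trait name used in the output row.
#' @param category Free-text trait grouping.
#' @param opts \code{\link{scan_options}}.
#' @return One-row data.frame (see \code{\link{run_phewas}} for columns).
#' @export
scan_trait <- function(score, values, kind = NULL, covariates = NULL,
                       trait = "trait", category = "", opts = scan_options()) {
  kind <- kind %||% infer_trait_type(values,
                                     max_ordered_levels = opts$max_ordered_levels)
  keep <- !is.na(values) & !is.na(score)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
    cv <- covariates[keep, , drop = FALSE]
  } else cv <- NULL
  y <- values[keep]
  s <- score[keep]
  n <- length(y)
  if (kind == "constant" || length(unique(y)) < 2)
    return(scan_result_row(trait, n = n, category = category,
                           skip_reason = "no variation"))

  fit_wald <- function(est, sd) {
    z <- est / sd
    scan_result_row(trait, test = NA, n = n, beta = est, se = sd,
                    pval = 2 * stats::pnorm(-abs(z)), category = category)
  }

  res <- tryCatch(switch(kind,
    continuous = {
      yt <- inverse_normal_transform(y, offset = opts$int_offset)
      X <- cbind(1, score = s, cv)
      f <- stats::lm.fit(X, yt)
      df <- n - ncol(X)
      sigma2 <- sum(f$residuals^2) / df
      xtx_inv <- chol2inv(qr.R(f$qr))
      j <- which(f$qr$pivot == 2)  # position of the score column after pivoting
      out <- fit_wald(f$coefficients["score"], sqrt(sigma2 * xtx_inv[j, j]))
      out$test <- "linear"; out
    },
    binary = {
      yy <- as.integer(y == max(y))
      if (min(sum(yy), sum(1 - yy)) < opts$min_cases)
        return(scan_result_row(trait, n = n, category = category,
                               skip_reason = sprintf("fewer than %d cases",
                                                     opts$min_cases)))
      X <- cbind(1, score = s, cv)
      g <- stats::glm.fit(X, yy, family = stats::binomial())
      if (!g$converged) stop("logistic regression did not converge")
      co <- glm_fit_coef(g)
      out <- fit_wald(co[2, 1], co[2, 2])
      out$test <- "logistic"; out
    },
    ordered = {
      fo <- factor(y, ordered = TRUE)
      dat <- data.frame(.y = fo, .s = s)
      form <- .y ~ .s
      if (!is.null(cv)) {
        dat <- cbind(dat, as.data.frame(cv))
        form <- stats::as.formula(paste(".y ~ .s +",
                                        paste(colnames(as.data.frame(cv)),
                                              collapse = " + ")))
      }
      f <- MASS::polr(form, data = dat, Hess = TRUE)
      sm <- sqrt(diag(solve(f$Hessian)))
      out <- fit_wald(f$coefficients[".s"], sm[".s"])
      out$test <- "ordered_logistic"; out
    },
    unordered = {
      fy <- factor(y)
      fy <- stats::relevel(fy, ref = names(which.max(table(fy))))
      Xnull <- if (is.null(cv)) data.frame(row.names = seq_len(n))
               else as.data.frame(cv)
      dat <- cbind(data.frame(.y = fy, .s = s), Xnull)
      rhs_null <- if (is.null(cv)) "1" else
        paste(colnames(Xnull), collapse = " + ")
      f1 <- nnet::multinom(stats::as.formula(paste(".y ~ .s +", rhs_null)),
                           data = dat, trace = FALSE, maxit = 200)
      f0 <- nnet::multinom(stats::as.formula(paste(".y ~", rhs_null)),
                           data = dat, trace = FALSE, maxit = 200)
      df <- nlevels(fy) - 1
      lrt <- f0$deviance - f1$deviance
      out <- scan_result_row(trait, test = "multinomial", n = n,
                             pval = stats::pchisq(lrt, df, lower.tail = FALSE),
                             category = category)
      out
    }),
    error = function(e) scan_result_row(trait, n = n, category = category,
                                        skip_reason = paste("fit failed:",
                                                            conditionMessage(e))))
  res
}

#' Rank-based FDR threshold
#'
#' Sorts the p-values ascending and finds the largest rank \eqn{r} with
#' \eqn{p_{(r)} < q \cdot r / n} (strict inequality, as the procedure is
#' stated for phenome scans); the discovery threshold is then
#' \eqn{P_t = q \cdot r / n} and every test with \eqn{p < P_t} is flagged.
#' With no passing rank the threshold is reported as 0 and nothing is
#' discovered. Note the strict inequality can differ from step-up
#' Benjamini-Hochberg (which uses \eqn{\le}) when p-values tie exactly with
#' their rank threshold.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param q Target false discovery rate; default 0.05.
#' @return List of class \code{fdr_threshold}: \code{threshold},
#'   \code{rank}, \code{discoveries} (logical, input order), \code{n}.
#' @examples
#' fdr_threshold(c(0.001, 0.01, 0.02, 0.03, 0.2))  # rank 4, threshold 0.04
#' @export
fdr_threshold <- function(pvalues, q = 0.05) {
  if (length(pvalues) < 1) abort_input("need at least one p-value")
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    abort_input("p-values must lie in (0, 1]")
  n <- length(pvalues)
  ps <- sort(pvalues)
  pass <- ps < q * seq_len(n) / n
  rank <- if (any(pass)) max(which(pass)) else 0L
  threshold <- if (rank > 0) q * rank / n else 0
  structure(list(threshold = threshold, rank = as.integer(rank),
                 discoveries = pvalues < threshold, n = n, q = q),
            class = "fdr_threshold")
}

#' Bonferroni-corrected p-value threshold
#' @param n_tests Number of tests performed (>= 1).
#' @param alpha Family-wise error rate; default 0.05.
#' @return \code{alpha / n_tests}.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || length(n_tests) != 1 || n_tests < 1)
    abort_input("`n_tests` must be >= 1")
  alpha / n_tests
}

#' Expected vs observed -log10 p-values for a QQ plot
#'
#' @param pvalues Numeric p-values in (0, 1].
#' @param floor Smallest representable double used to flag underflowing
#'   p-values (default \code{.Machine$double.xmin}, about 2.23e-308).
#' @return data.frame with \code{expected}, \code{observed} (-log10, both
#'   ascending in significance) and \code{at_floor}.
#' @export
qq_data <- function(pvalues, floor = .Machine$double.xmin) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    abort_input("p-values must lie in [0, 1]")
  at_floor <- pvalues <= floor
  pvalues <- pmax(pvalues, floor)
  ord <- order(pvalues)
  n <- length(pvalues)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(pvalues[ord]),
             at_floor = at_floor[ord])
}

#' Run the phenome-wide scan
#'
#' Tests every phenome trait against the score (deterministic alphabetical
#' trait order), then summarizes multiplicity control over the tested
#' subset: the rank-based FDR threshold and the Bonferroni threshold.
#' Skipped traits (no variation, too few cases, failed fits) are retained
#' with their reason and excluded from the threshold arithmetic.
#'
#' @param cohort An \code{mr_cohort} with a filled phenome.
#' @param score Per-individual instrument score.
#' @param traits Trait names to scan; default all phenome columns.
#' @param covariates Covariate matrix; default age + 10 PCs.
#' @param opts \code{\link{scan_options}}.
#' @return List of class \code{phewas_result}: \code{results} (data.frame
#'   with trait, category, test, n, beta, se, pval, fdr_pass, bonf_pass,
#'   skip_reason) and \code{thresholds} (\code{threshold_report}: n_tests,
#'   fdr_threshold, fdr_rank, n_fdr, bonferroni_threshold, n_bonf).
#' @export
run_phewas <- function(cohort, score, traits = NULL,
                       covariates = default_covariates(cohort),
                       opts = scan_options()) {
  traits <- traits %||% names(cohort$phenome)
  if (length(traits) == 0) abort_input("the phenome is empty")
  traits <- sort(traits)
  rows <- lapply(traits, function(tr) {
    spec <- cohort$trait_specs[[tr]]
    kind <- if (!is.null(spec)) spec$kind else NULL
    cat_ <- if (!is.null(spec)) spec$category else ""
    scan_trait(score, cohort$phenome[[tr]], kind = kind,
               covariates = covariates, trait = tr, category = cat_,
               opts = opts)
  })
  results <- do.call(rbind, rows)
  tested <- !is.na(results$pval)
  results$fdr_pass <- FALSE
  results$bonf_pass <- FALSE
  if (any(tested)) {
    fdr <- fdr_threshold(results$pval[tested], q = opts$fdr_q)
    bonf <- bonferroni_threshold(sum(tested), alpha = opts$alpha)
    results$fdr_pass[tested] <- fdr$discoveries
    results$bonf_pass[tested] <- results$pval[tested] < bonf
    thresholds <- structure(list(
      n_tests = fdr$n, fdr_threshold = fdr$threshold, fdr_rank = fdr$rank,
      n_fdr = sum(results$fdr_pass), bonferroni_threshold = bonf,
      n_bonf = sum(results$bonf_pass)), class = "threshold_report")
  } else {
    thresholds <- structure(list(n_tests = 0L, fdr_threshold = 0,
                                 fdr_rank = 0L, n_fdr = 0L,
                                 bonferroni_threshold = NA_real_,
                                 n_bonf = 0L), class = "threshold_report")
  }
  structure(list(results = results, thresholds = thresholds),
            class = "phewas_result")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("%d tests: FDR threshold %.3g (rank %d, %d discoveries); Bonferroni %.3g (%d discoveries)\n",
              x$n_tests, x$fdr_threshold, x$fdr_rank, x$n_fdr,
              x$bonferroni_threshold, x$n_bonf))
  invisible(x)
}

#' @export
print.phewas_result <- function(x, ...) {
  cat(sprintf("<phewas_result> %d trait(s) scanned\n", nrow(x$results)))
  print(x$thresholds)
  invisible(x)
}
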