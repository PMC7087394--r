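#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects horizontal pleiotropy as over-dispersion of the per-variant
#' outcome effects around the IVW-predicted values. For each variant
#' \eqn{i}, a leave-one-out fixed-effect IVW slope (weighted regression of
#' \eqn{\beta_{out}} on \eqn{\beta_{exp}} through the origin, weights
#' \eqn{1/se_{out}^2}) predicts \eqn{\hat\beta_{out,i}}; the observed
#' statistic is the weighted residual sum of squares
#' \eqn{RSS = \sum_i (\beta_{out,i} - \hat\beta_{out,i})^2 / se_{out,i}^2}.
#'
#' The null distribution is simulated parametrically: outcome effects are
#' redrawn from \eqn{N(\hat\beta_{out,i}, se_{out,i}^2)} and the whole
#' leave-one-out RSS recomputed, giving the global p-value
#' \eqn{(1 + \#\{RSS^* \ge RSS\}) / (n_{sim} + 1)}. Per-variant outlier
#' p-values compare each observed squared residual with its simulated null,
#' Bonferroni-corrected across variants; variants with corrected p below
#' \code{outlier_alpha} are flagged. The outlier-adjusted estimate is IVW on
#' the remaining variants, and the distortion test compares the observed
#' displacement \eqn{(\hat\beta_{adj} - \hat\beta_{raw})/|\hat\beta_{raw}|}
#' with the displacement obtained by removing equally many variants at
#' random. Following the published decision rule, the adjusted estimate is
#' recommended (\code{use_adjusted}) only when both the global and the
#' distortion p-values are below 0.05.
#'
#' @param mr_input An \code{mr_input} with >= 4 variants.
#' @param n_sim Number of parametric simulations; default 1000.
#' @param seed Integer seed.
#' @param outlier_alpha Significance level for the Bonferroni-corrected
#'   outlier test; default 0.05.
#' @param ivw_model Model for the raw/adjusted IVW estimates; default
#'   "random".
#' @return A list of class \code{presso_result}: \code{global_rss},
#'   \code{global_p}, \code{outlier_p} (named, Bonferroni-corrected),
#'   \code{outliers}, \code{beta_raw}, \code{beta_adjusted},
#'   \code{distortion_p}, \code{use_adjusted}, \code{n_sim}.
#' @export
mr_presso <- function(mr_input, n_sim = 1000, seed = 1, outlier_alpha = 0.05,
                      ivw_model = "random") {
  k <- nrow(mr_input)
  if (k < 4)
    abort_input("MR-PRESSO needs at least 4 variants",
                class = "mrphewas_method_error")
  x <- mr_input$beta_exp
  y <- mr_input$beta_out
  w <- 1 / mr_input$se_out^2

  loo_pred <- function(yv) {
    sxy <- sum(w * x * yv); sxx <- sum(w * x^2)
    slope_loo <- (sxy - w * x * yv) / (sxx - w * x^2)
    slope_loo * x
  }
  rss_of <- function(yv) {
    pred <- loo_pred(yv)
    sum(w * (yv - pred)^2)
  }

  pred_obs <- loo_pred(y)
  res_obs <- w * (y - pred_obs)^2
  rss_obs <- sum(res_obs)

  set.seed(substream_seed(seed, "presso"))
  sim_rss <- numeric(n_sim)
  exceed <- matrix(0L, n_sim, k)
  for (b in seq_len(n_sim)) {
    ys <- stats::rnorm(k, pred_obs, mr_input$se_out)
    pred_s <- loo_pred(ys)
    res_s <- w * (ys - pred_s)^2
    sim_rss[b] <- sum(res_s)
    exceed[b, ] <- as.integer(res_s >= res_obs)
  }
  global_p <- (1 + sum(sim_rss >= rss_obs)) / (n_sim + 1)

  outlier_p_raw <- (1 + colSums(exceed)) / (n_sim + 1)
  outlier_p <- pmin(1, outlier_p_raw * k)
  names(outlier_p) <- mr_input$rsid
  outliers <- mr_input$rsid[outlier_p < outlier_alpha]

  beta_raw <- mr_ivw(mr_input, model = ivw_model)
  beta_adjusted <- NULL
  distortion_p <- NA_real_
  if (length(outliers) > 0 && k - length(outliers) >= 2) {
    keep <- !(mr_input$rsid %in% outliers)
    beta_adjusted <- mr_ivw(mr_input[keep, , drop = FALSE], model = ivw_model)
    d_obs <- (beta_adjusted$beta - beta_raw$beta) / abs(beta_raw$beta)
    n_out <- length(outliers)
    d_sim <- vapply(seq_len(min(n_sim, 1000)), function(b) {
      drop_idx <- sample.int(k, n_out)
      b_sub <- mr_ivw(mr_input[-drop_idx, , drop = FALSE], model = ivw_model)
      (b_sub$beta - beta_raw$beta) / abs(beta_raw$beta)
    }, numeric(1))
    distortion_p <- mean(abs(d_sim) >= abs(d_obs))
    distortion_p <- max(distortion_p, 1 / (length(d_sim) + 1))
  }
  structure(list(global_rss = rss_obs, global_p = global_p,
                 outlier_p = outlier_p, outliers = outliers,
                 beta_raw = beta_raw, beta_adjusted = beta_adjusted,
                 distortion_p = distortion_p,
                 use_adjusted = isTRUE(global_p < 0.05 && distortion_p < 0.05),
                 n_sim = n_sim), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.3f, global p = %.3g, %d outlier(s)\n",
              x$global_rss, x$global_p, length(x$outliers)))
  if (length(x$outliers))
    cat("  outliers:", paste(x$outliers, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_p))
  cat(sprintf("  raw beta = %.4f%s\n", x$beta_raw$beta,
              if (!is.null(x$beta_adjusted))
                sprintf("; adjusted beta = %.4f (%s)", x$beta_adjusted$beta,
                        if (x$use_adjusted) "reported" else "not reported")
              else ""))
  invisible(x)
}
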