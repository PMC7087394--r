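#' Weighted genetic risk score oriented to the exposure-decreasing allele
#'
#' Computes, per individual, a weighted sum of exposure-decreasing allele
#' counts: each variant is oriented so that the counted allele lowers the
#' exposure (for a variant whose effect allele raises it, the dosage is
#' flipped to \code{2 - d}), and the absolute per-allele weight is applied.
#' A higher score therefore predicts a genetically earlier menarche (lower
#' exposure). The score is invariant to relabelling effect/other alleles.
#'
#' @param dosages Numeric matrix (individuals x variants) with rsid column
#'   names, or an \code{mr_cohort}.
#' @param weights Named numeric vector (rsid -> beta_exposure, years per
#'   effect allele) or a \code{variant_panel}.
#' @return Numeric vector of per-individual scores.
#' @examples
#' d <- matrix(0:2, 3, 1, dimnames = list(NULL, "rs1"))
#' compute_grs(d, c(rs1 = -0.1))  # 0, 0.1, 0.2
#' @export
compute_grs <- function(dosages, weights) {
  if (inherits(dosages, "mr_cohort")) dosages <- dosages$dosages
  if (inherits(weights, "variant_panel") || is.data.frame(weights))
    weights <- stats::setNames(weights$beta_exposure, weights$rsid)
  unknown <- setdiff(names(weights), colnames(dosages))
  if (length(unknown))
    abort_input(paste0("weight rsid(s) not in dosage columns: ",
                       paste(unknown, collapse = ", ")))
  d <- dosages[, names(weights), drop = FALSE]
  # orient: beta > 0 means the effect allele delays menarche; count the
  # opposite allele instead
  flip <- weights > 0
  d[, flip] <- 2 - d[, flip, drop = FALSE]
  drop(d %*% abs(weights))
}

#' Instrument strength: incremental R-squared and partial F
#'
#' Adds the score to a covariate-only linear model of the exposure and
#' reports the incremental variance explained
#' \eqn{(RSS_0 - RSS_1)/TSS} and the partial F statistic
#' \eqn{(RSS_0 - RSS_1) / (RSS_1 / (n - p - 2))} for the score term.
#'
#' @param score Per-individual instrument score.
#' @param exposure Exposure vector.
#' @param covariates Optional covariate matrix.
#' @return List of class \code{instrument_strength}: \code{r_squared},
#'   \code{f_statistic}, \code{n}.
#' @export
instrument_strength <- function(score, exposure, covariates = NULL) {
  keep <- !is.na(score) & !is.na(exposure)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  score <- score[keep]; exposure <- exposure[keep]
  n <- length(score)
  p <- if (is.null(covariates)) 0 else ncol(covariates)
  if (n <= p + 2) abort_input("too few observations for the model")
  if (stats::var(score) == 0) {
    warning("score has zero variance; r_squared defined as 0")
    res <- list(r_squared = 0, f_statistic = 0, n = n)
    class(res) <- "instrument_strength"
    return(res)
  }
  ry <- drop(residualize(exposure, covariates))
  rs <- drop(residualize(score, covariates))
  tss <- sum((exposure - mean(exposure))^2)
  rss0 <- sum(ry^2)
  b <- sum(rs * ry) / sum(rs^2)
  rss1 <- rss0 - b^2 * sum(rs^2)
  res <- list(r_squared = (rss0 - rss1) / tss,
              f_statistic = (rss0 - rss1) / (rss1 / (n - p - 2)),
              n = n)
  class(res) <- "instrument_strength"
  res
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: R^2 = %.4f (%s), F = %.1f, n = %d\n",
              x$r_squared, fmt_pct(x$r_squared), x$f_statistic, x$n))
  invisible(x)
}

new_variant_set <- function(label, panel, excluded, reason) {
  excl <- panel$rsid %in% excluded
  structure(list(
    label = label,
    included_rsids = panel$rsid[!excl],
    excluded_rsids = panel$rsid[excl],
    reason = stats::setNames(rep_len(reason, sum(excl)), panel$rsid[excl])
  ), class = "grs_variant_set")
}

#' @export
print.grs_variant_set <- function(x, ...) {
  cat(sprintf("<grs_variant_set '%s'> %d included, %d excluded\n",
              x$label, length(x$included_rsids), length(x$excluded_rsids)))
  invisible(x)
}

#' Steiger filtering against a competing trait
#'
#' Excludes every variant whose squared sample correlation with the
#' competing trait (default adult BMI) strictly exceeds its squared
#' correlation with the exposure -- i.e. variants that explain more of the
#' variation in the competing trait, the signature of horizontal pleiotropy
#' acting through it. Ties (to machine precision) are kept.
#'
#' @param cohort An \code{mr_cohort}.
#' @param panel Variant panel (defaults to the cohort's panel).
#' @param competing_trait Name resolvable by the cohort ("adult_bmi",
#'   "child_bmi", "height", "exposure", or a phenome column).
#' @return A \code{grs_variant_set} labelled "steiger". The per-variant
#'   r-squared values are attached as attribute \code{"r2_table"}.
#' @export
steiger_filter <- function(cohort, panel = cohort$panel,
                           competing_trait = "adult_bmi") {
  comp <- tryCatch(resolve_trait(cohort, competing_trait),
                   error = function(e) abort_input(
                     sprintf("competing trait '%s' not available", competing_trait)))
  d <- cohort$dosages[, panel$rsid, drop = FALSE]
  r2_exp <- drop(stats::cor(d, cohort$exposure))^2
  r2_comp <- drop(stats::cor(d, comp))^2
  excl <- r2_comp > r2_exp
  vs <- new_variant_set("steiger", panel, panel$rsid[excl],
                        sprintf("r2 %s > r2 exposure", competing_trait))
  attr(vs, "r2_table") <- data.frame(rsid = panel$rsid, r2_exposure = r2_exp,
                                     r2_competing = r2_comp,
                                     excluded = excl)
  vs
}

#' Proximity exclusion around competing-trait association hits
#'
#' Excludes a variant if it matches a hit rsid, or lies on the same
#' chromosome within \code{window_bp} of any hit position. The boundary is
#' inclusive: a variant exactly \code{window_bp} away is excluded ("within"
#' reading of the window; configurable via \code{window_bp}).
#'
#' @param panel Variant panel.
#' @param reference_hits data.frame with columns \code{chrom}, \code{pos}
#'   (1-based) and optionally \code{rsid}.
#' @param window_bp Window in base pairs (>= 0), default 500000.
#' @param label Label for the returned set.
#' @return A \code{grs_variant_set}.
#' @export
proximity_filter <- function(panel, reference_hits, window_bp = 500000L,
                             label = "proximity") {
  assert_scalar_number(window_bp, "window_bp", 0, Inf)
  if (is.null(reference_hits) || nrow(as.data.frame(reference_hits)) == 0)
    return(new_variant_set(label, panel, character(), character()))
  hits <- as.data.frame(reference_hits)
  excl <- logical(nrow(panel))
  for (i in seq_len(nrow(hits))) {
    near <- panel$chrom == hits$chrom[i] &
      abs(panel$pos - hits$pos[i]) <= window_bp
    if (!is.null(hits$rsid) && !is.na(hits$rsid[i]))
      near <- near | panel$rsid == hits$rsid[i]
    excl <- excl | near
  }
  new_variant_set(label, panel, panel$rsid[excl],
                  sprintf("within %d bp of a reference hit", as.integer(window_bp)))
}

#' Build the four instrument variant sets
#'
#' Returns the full set plus the three filtered alternatives used in the
#' sensitivity scans: Steiger-filtered (variants explaining more competing-
#' trait than exposure variance removed), childhood-BMI-hit-excluded, and
#' any-BMI-hit-excluded (childhood and adult hits combined).
#'
#' @param panel Variant panel.
#' @param cohort An \code{mr_cohort} (used for Steiger filtering); NULL skips
#'   the Steiger set.
#' @param child_hits,adult_hits Hit tables as in \code{\link{proximity_filter}}
#'   (may be NULL/empty).
#' @param window_bp Proximity window.
#' @param competing_trait Competing trait for Steiger filtering.
#' @return Named list of \code{grs_variant_set}: all, steiger, child_bmi, bmi.
#' @export
build_instrument_sets <- function(panel, cohort = NULL, child_hits = NULL,
                                  adult_hits = NULL, window_bp = 500000L,
                                  competing_trait = "adult_bmi") {
  norm_hits <- function(h) {
    if (is.null(h)) h <- data.frame(chrom = integer(), pos = integer())
    h <- as.data.frame(h)
    if (is.null(h$rsid)) h$rsid <- rep(NA_character_, nrow(h))
    h[c("rsid", "chrom", "pos")]
  }
  ch <- norm_hits(child_hits)
  ad <- norm_hits(adult_hits)
  both <- unique(rbind(ch, ad))
  sets <- list(
    all = new_variant_set("all", panel, character(), character()),
    steiger = if (is.null(cohort))
      new_variant_set("steiger", panel, character(), character())
    else {
      s <- steiger_filter(cohort, panel, competing_trait); s
    },
    child_bmi = proximity_filter(panel, ch, window_bp, label = "child_bmi"),
    bmi = proximity_filter(panel, both, window_bp, label = "bmi")
  )
  sets
}

#' Subset panel to an instrument set
#' @param panel Variant panel.
#' @param set A \code{grs_variant_set}.
#' @return The panel restricted to the set's included rsids.
#' @export
apply_variant_set <- function(panel, set) {
  out <- panel[panel$rsid %in% set$included_rsids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
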