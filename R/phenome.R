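#' Specify one phenome trait for the simulator
#'
#' A trait is generated from a latent continuous variable
#' \deqn{L = \beta [ (1 - w)\,(X - \bar X) + w\,(B - \bar B) ] +
#'       \sum_j d_j \gamma_j + \epsilon,}
#' where \eqn{X} is the exposure, \eqn{B} adult BMI (so \eqn{w} is the
#' fraction of the causal effect routed through the BMI mediator),
#' \eqn{d_j \gamma_j} are direct per-allele (horizontally pleiotropic)
#' variant effects, and \eqn{\epsilon \sim N(0, \code{noise_sd}^2)}.
#' Binary and ordered traits threshold the latent at cut-points solved from
#' the requested marginal frequencies; unordered traits use a multinomial
#' logit whose level-specific slopes on the latent are centred at zero.
#'
#' @param name Unique trait name.
#' @param kind One of "continuous", "binary", "ordered", "unordered".
#' @param beta_menarche Causal effect of the exposure on the latent scale.
#' @param mediation_via_bmi Fraction of the effect routed through adult BMI,
#'   in [0, 1].
#' @param pleiotropy Named numeric vector: rsid -> direct per-allele effect.
#' @param noise_sd Residual SD of the latent trait.
#' @param prevalence Case fraction (binary traits).
#' @param levels Number of categories, or a probability vector summing to 1
#'   (ordered / unordered traits).
#' @param missing_rate Fraction of values set missing completely at random.
#' @param category Free-text grouping used in scan output.
#' @return A list of class \code{trait_spec}.
#' @export
trait_spec <- function(name, kind = c("continuous", "binary", "ordered",
                                      "unordered"),
                       beta_menarche = 0, mediation_via_bmi = 0,
                       pleiotropy = NULL, noise_sd = 1,
                       prevalence = NULL, levels = NULL,
                       missing_rate = 0, category = "synthetic") {
  kind <- match.arg(kind)
  assert_scalar_number(mediation_via_bmi, "mediation_via_bmi", 0, 1)
  assert_scalar_number(missing_rate, "missing_rate", 0, 1)
  if (kind == "binary") {
    prevalence <- prevalence %||% 0.5
    assert_scalar_number(prevalence, "prevalence", 0, 1, strict = TRUE)
  }
  if (kind %in% c("ordered", "unordered")) {
    levels <- levels %||% 3
    if (length(levels) == 1) {
      if (levels < 2) abort_input("`levels` must be >= 2")
    } else if (abs(sum(levels) - 1) > 1e-8) {
      abort_input("`levels` given as probabilities must sum to 1")
    }
  }
  structure(list(name = name, kind = kind, beta_menarche = beta_menarche,
                 mediation_via_bmi = mediation_via_bmi,
                 pleiotropy = pleiotropy, noise_sd = noise_sd,
                 prevalence = prevalence, levels = levels,
                 missing_rate = missing_rate, category = category),
            class = "trait_spec")
}

trait_latent <- function(cohort, spec) {
  w <- spec$mediation_via_bmi
  x <- cohort$exposure - mean(cohort$exposure)
  b <- cohort$adult_bmi - mean(cohort$adult_bmi)
  lat <- spec$beta_menarche * ((1 - w) * x + w * b)
  if (length(spec$pleiotropy)) {
    rs <- names(spec$pleiotropy)
    unknown <- setdiff(rs, colnames(cohort$dosages))
    if (length(unknown))
      abort_input(paste0("pleiotropy rsids not in cohort: ",
                         paste(unknown, collapse = ", ")))
    lat <- lat + drop(cohort$dosages[, rs, drop = FALSE] %*%
                        unname(spec$pleiotropy))
  }
  lat + stats::rnorm(cohort$n, 0, spec$noise_sd)
}

level_probs <- function(levels) {
  if (length(levels) == 1) rep(1 / levels, levels) else as.numeric(levels)
}

#' Fill the cohort phenome from a list of trait specifications
#'
#' Continuous traits are the latent variable itself; binary traits threshold
#' it at the empirical (1 - prevalence) quantile; ordered traits cut at the
#' quantiles of the cumulative level probabilities (integer codes 1..L);
#' unordered traits draw from a multinomial logit with intercepts
#' \eqn{\log p_l} and level slopes \eqn{(l - (L+1)/2)} on the latent, so a
#' null latent reproduces the requested marginal frequencies. Each trait uses
#' its own random substream: adding a trait does not perturb earlier draws.
#'
#' @param cohort An \code{mr_cohort}.
#' @param specs List of \code{\link{trait_spec}} objects with unique names.
#' @param seed Integer seed.
#' @return The cohort with \code{phenome} (and \code{trait_specs}) filled.
#' @export
simulate_phenome <- function(cohort, specs, seed) {
  if (inherits(specs, "trait_spec")) specs <- list(specs)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    abort_input(paste0("duplicate trait name(s): ",
                       paste(unique(nm[duplicated(nm)]), collapse = ", ")),
                class = "mrphewas_config_error")
  phen <- cohort$phenome
  for (spec in specs) {
    set.seed(substream_seed(seed, paste0("trait:", spec$name)))
    lat <- trait_latent(cohort, spec)
    val <- switch(spec$kind,
      continuous = lat,
      binary = as.integer(lat > stats::quantile(lat, 1 - spec$prevalence)),
      ordered = {
        p <- level_probs(spec$levels)
        cuts <- stats::quantile(lat, cumsum(p)[-length(p)])
        as.integer(findInterval(lat, cuts, left.open = TRUE) + 1L)
      },
      unordered = {
        p <- level_probs(spec$levels)
        L <- length(p)
        slopes <- seq_len(L) - (L + 1) / 2
        eta <- outer(lat, slopes) + rep(log(p), each = cohort$n)
        eta <- eta - apply(eta, 1, max)
        pr <- exp(eta) / rowSums(exp(eta))
        u <- stats::runif(cohort$n)
        lev <- max.col(u < t(apply(pr, 1, cumsum)), ties.method = "first")
        paste0("L", lev)
      })
    if (spec$missing_rate > 0)
      val[stats::runif(cohort$n) < spec$missing_rate] <- NA
    phen[[spec$name]] <- val
  }
  cohort$phenome <- phen
  cohort$trait_specs <- c(cohort$trait_specs, stats::setNames(specs, nm))
  cohort
}
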