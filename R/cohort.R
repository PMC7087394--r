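#' Generator configuration for a synthetic cohort
#'
#' Bundles the parameters of the causal structure the simulator emulates:
#' variants affect the exposure (age at menarche) additively; a designated
#' subset may also affect childhood BMI directly (horizontal pleiotropy);
#' childhood BMI tracks into adult BMI, and the exposure itself feeds adult
#' BMI (vertical pleiotropy); a latent confounder loads on exposure and both
#' BMI measures. Defaults reproduce a biobank-like female cohort: exposure
#' mean 12.9 y, SD 1.6 y; adult BMI mean 27 kg/m^2; height mean 162.5 cm.
#'
#' @param exposure_mean,exposure_sd Mean and total SD of the exposure (years).
#' @param child_bmi_mean,child_bmi_sd Childhood BMI marginal moments (kg/m^2).
#' @param adult_bmi_mean,adult_bmi_sd Adult BMI marginal moments (kg/m^2).
#' @param height_mean,height_sd Adult height moments (cm).
#' @param beta_child_to_adult Tracking coefficient, adult BMI per unit
#'   childhood BMI.
#' @param beta_exposure_to_adult_bmi Vertical path: adult BMI change per year
#'   of exposure (negative = earlier menarche, higher adult BMI).
#' @param beta_exposure_to_height Height change per year of exposure.
#' @param pleiotropy_rsids Character vector of panel rsids with direct
#'   (horizontal) effects on childhood BMI.
#' @param pleiotropy_beta Per-allele childhood-BMI effect (kg/m^2) shared by
#'   \code{pleiotropy_rsids} (recycled).
#' @param confounder_exposure,confounder_bmi Loadings of a standard-normal
#'   latent confounder on the exposure (years) and the BMI variables (kg/m^2).
#' @param age_range Recruitment age range (years), sampled uniformly.
#' @return A list of class \code{cohort_params}.
#' @export
cohort_params <- function(exposure_mean = 12.9, exposure_sd = 1.6,
                          child_bmi_mean = 17.5, child_bmi_sd = 2.5,
                          adult_bmi_mean = 27.0, adult_bmi_sd = 4.5,
                          height_mean = 162.5, height_sd = 6.3,
                          beta_child_to_adult = 0.9,
                          beta_exposure_to_adult_bmi = -0.35,
                          beta_exposure_to_height = 0.4,
                          pleiotropy_rsids = character(),
                          pleiotropy_beta = 0.3,
                          confounder_exposure = 0.25,
                          confounder_bmi = 0.5,
                          age_range = c(40, 69)) {
  assert_scalar_number(exposure_sd, "exposure_sd", 0, Inf, strict = TRUE)
  p <- as.list(environment())
  class(p) <- "cohort_params"
  p
}

#' Simulate an individual-level cohort with the assumed causal structure
#'
#' Genotype dosages are Binomial(2, eaf) per variant under Hardy-Weinberg and
#' linkage equilibrium (the instrument set is treated as independent signals).
#' The exposure is \code{mean + sum(dosage * beta_exposure) + c_U * U + e},
#' with the residual SD chosen so the total SD matches the configured value.
#' Childhood BMI receives direct per-allele effects from the configured
#' horizontal-pleiotropy subset; adult BMI is a linear function of childhood
#' BMI and the exposure (the vertical path) plus noise. The result is a pure
#' function of \code{(panel, params, seed)}.
#'
#' @param panel A \code{variant_panel}.
#' @param n Number of individuals (>= 1).
#' @param params A \code{\link{cohort_params}} object.
#' @param seed Integer seed.
#' @return A list of class \code{mr_cohort} with elements \code{n},
#'   \code{panel}, \code{dosages} (n x m matrix, columns named by rsid),
#'   \code{exposure}, \code{child_bmi}, \code{adult_bmi}, \code{height},
#'   \code{age}, \code{pcs} (n x 10, mean-centred), \code{confounder},
#'   \code{phenome} (initially empty data.frame), \code{params}, \code{seed}.
#' @examples
#' pan <- simulate_panel(10, seed = 1)
#' ch <- simulate_cohort(pan, 500, seed = 1)
#' c(mean(ch$exposure), sd(ch$exposure))
#' @export
simulate_cohort <- function(panel, n, params = cohort_params(), seed) {
  validate_panel(panel)
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1)
    abort_input("`n` must be an integer >= 1")
  n <- as.integer(n)
  if (!inherits(params, "cohort_params"))
    abort_input("`params` must be created by cohort_params()")

  m <- nrow(panel)
  set.seed(substream_seed(seed, "genotypes"))
  dosages <- matrix(stats::rbinom(n * m, 2L, rep(panel$eaf, each = n)),
                    nrow = n, ncol = m,
                    dimnames = list(NULL, panel$rsid))

  set.seed(substream_seed(seed, "phenotypes"))
  U <- stats::rnorm(n)

  # centre the genetic component at its expectation so the configured mean
  # is the marginal exposure mean
  g <- drop(dosages %*% panel$beta_exposure) -
    2 * sum(panel$eaf * panel$beta_exposure)
  var_g <- sum(2 * panel$eaf * (1 - panel$eaf) * panel$beta_exposure^2)
  resid_var <- params$exposure_sd^2 - var_g - params$confounder_exposure^2
  if (resid_var < 0)
    abort_input("genetic + confounder variance exceeds the target exposure variance")
  exposure <- params$exposure_mean + g +
    params$confounder_exposure * U + stats::rnorm(n, 0, sqrt(resid_var))

  # childhood BMI: horizontal pleiotropy enters here
  pleio <- rep(0, n)
  pr <- params$pleiotropy_rsids
  if (length(pr)) {
    unknown <- setdiff(pr, panel$rsid)
    if (length(unknown))
      abort_input(paste0("pleiotropy_rsids not in panel: ",
                         paste(unknown, collapse = ", ")))
    pb <- rep_len(params$pleiotropy_beta, length(pr))
    pleio <- drop(dosages[, pr, drop = FALSE] %*% pb) -
      2 * sum(panel$eaf[match(pr, panel$rsid)] * pb)
  }
  child_resid <- sqrt(max(params$child_bmi_sd^2 - params$confounder_bmi^2, 0.01))
  child_bmi <- params$child_bmi_mean + pleio + params$confounder_bmi * U +
    stats::rnorm(n, 0, child_resid)

  # adult BMI: tracking from childhood plus the vertical exposure path
  adult_struct <- params$beta_child_to_adult * (child_bmi - params$child_bmi_mean) +
    params$beta_exposure_to_adult_bmi * (exposure - params$exposure_mean) +
    params$confounder_bmi * U
  adult_resid <- sqrt(max(params$adult_bmi_sd^2 - stats::var(adult_struct), 0.25))
  adult_bmi <- params$adult_bmi_mean + adult_struct + stats::rnorm(n, 0, adult_resid)

  height <- params$height_mean +
    params$beta_exposure_to_height * (exposure - params$exposure_mean) +
    stats::rnorm(n, 0, params$height_sd)

  age <- round(stats::runif(n, params$age_range[1], params$age_range[2]))
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  pcs <- sweep(pcs, 2, colMeans(pcs))

  structure(list(
    n = n, panel = panel, dosages = dosages, exposure = exposure,
    child_bmi = child_bmi, adult_bmi = adult_bmi, height = height,
    age = age, pcs = pcs, confounder = U,
    phenome = data.frame(row.names = seq_len(n)),
    trait_specs = list(), params = params, seed = seed
  ), class = "mr_cohort")
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat(sprintf("<mr_cohort> %d individuals, %d variants, %d phenome trait(s)\n",
              x$n, ncol(x$dosages), ncol(x$phenome)))
  cat(sprintf("  exposure: mean %.2f, sd %.2f\n",
              mean(x$exposure), stats::sd(x$exposure)))
  invisible(x)
}

#' Standard scan covariates (age + 10 principal components)
#'
#' @param cohort An \code{mr_cohort}.
#' @param which Character subset of \code{c("age", "pcs")}.
#' @return A numeric matrix with one row per individual.
#' @export
default_covariates <- function(cohort, which = c("age", "pcs")) {
  parts <- list()
  if ("age" %in% which) parts$age <- cohort$age
  if ("pcs" %in% which) parts$pcs <- cohort$pcs
  do.call(cbind, parts)
}
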