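# Panel, cohort and phenome generators.

test_that("simulate_panel hits the analytic variance-explained target", {
  pan <- simulate_panel(360, seed = 11)
  r2 <- sum(2 * pan$eaf * (1 - pan$eaf) * pan$beta_exposure^2) / 1.6^2
  expect_equal(r2, 0.061, tolerance = 1e-10)
  expect_equal(panel_r2(pan), r2)

  # degenerate frequency bounds pin the eaf
  one <- simulate_panel(1, seed = 3, freq_low = 0.49, freq_high = 0.51)
  expect_true(abs(one$eaf - 0.5) < 0.01)
})

test_that("simulate_panel validates its arguments", {
  expect_error(simulate_panel(0, seed = 1), class = "mrphewas_input_error")
  expect_error(simulate_panel(5, seed = 1, freq_low = 0.5, freq_high = 0.2),
               class = "mrphewas_input_error")
  expect_error(simulate_panel(5, seed = 1, freq_low = 0, freq_high = 0.5),
               class = "mrphewas_input_error")
})

test_that("panel variants are spaced beyond the proximity window", {
  pan <- simulate_panel(100, seed = 7)
  for (c in unique(pan$chrom)) {
    pos <- sort(pan$pos[pan$chrom == c])
    if (length(pos) > 1) expect_true(all(diff(pos) > 500000))
  }
})

test_that("cohort matches configured exposure moments and is reproducible", {
  pan <- simulate_panel(60, seed = 21)
  coh <- simulate_cohort(pan, 100000, seed = 22)
  expect_lt(abs(mean(coh$exposure) - 12.9), 0.05)
  expect_lt(abs(sd(coh$exposure) - 1.6), 0.05)
  expect_true(all(coh$dosages %in% 0:2))
  expect_lt(max(abs(colMeans(coh$pcs))), 1e-12)

  # per-variant sample EAF within 3 binomial SDs of the panel value
  eaf_hat <- colMeans(coh$dosages) / 2
  band <- 3 * sqrt(pan$eaf * (1 - pan$eaf) / (2 * coh$n))
  expect_true(all(abs(eaf_hat - pan$eaf) <= band))

  coh2 <- simulate_cohort(pan, 100000, seed = 22)
  expect_identical(coh$dosages, coh2$dosages)
  expect_identical(coh$exposure, coh2$exposure)
  expect_identical(coh$adult_bmi, coh2$adult_bmi)
})

test_that("a null genetic architecture leaves the score uncorrelated", {
  pan <- simulate_panel(40, seed = 31)
  pan$beta_exposure <- rep(0, 40)
  # zero weights break the R2 budget; rebuild exposure from this null panel
  coh <- simulate_cohort(pan, 20000, seed = 32)
  grs <- drop(coh$dosages %*% rep(1, 40))  # any fixed weighting
  expect_lt(abs(cor(grs, coh$exposure)), 3 / sqrt(coh$n))
})

test_that("vertical and horizontal pleiotropy paths are wired as configured", {
  pan <- simulate_panel(30, seed = 41)
  prm <- cohort_params(pleiotropy_rsids = pan$rsid[1:3], pleiotropy_beta = 1.0)
  coh <- simulate_cohort(pan, 50000, prm, seed = 42)
  # horizontal: designated variants move childhood BMI
  r_child <- abs(cor(coh$dosages[, 1], coh$child_bmi))
  expect_gt(r_child, 0.1)
  expect_lt(abs(cor(coh$dosages[, 10], coh$child_bmi)), 3 / sqrt(coh$n))
  # vertical: exposure feeds adult BMI with the configured negative sign
  expect_lt(cor(coh$exposure, resid(lm(coh$adult_bmi ~ coh$child_bmi))), 0)
})

test_that("phenome traits honour their marginal specifications", {
  pan <- simulate_panel(20, seed = 51)
  coh <- simulate_cohort(pan, 20000, seed = 52)
  coh <- simulate_phenome(coh, list(
    trait_spec("bin_null", "binary", prevalence = 0.5),
    trait_spec("cont_copy", "continuous", beta_menarche = 1, noise_sd = 0),
    trait_spec("ord_null", "ordered", levels = 4),
    trait_spec("un_null", "unordered", levels = 3),
    trait_spec("tied", "ordered", levels = c(0.2, 0.3, 0.5))
  ), seed = 53)
  ph <- coh$phenome
  expect_lt(abs(mean(ph$bin_null) - 0.5), 2 / sqrt(coh$n))
  # beta=1, no mediation, no noise: the trait is an affine shift of exposure
  fit <- lm(ph$cont_copy ~ coh$exposure)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-10)
  expect_lt(max(abs(resid(fit))), 1e-8)
  expect_setequal(unique(ph$ord_null), 1:4)
  expect_setequal(unique(ph$un_null), c("L1", "L2", "L3"))
  expect_lt(abs(mean(ph$tied == 3) - 0.5), 2 / sqrt(coh$n))
})

test_that("trait substreams are independent of list order", {
  pan <- simulate_panel(10, seed = 61)
  coh <- simulate_cohort(pan, 1000, seed = 62)
  a <- simulate_phenome(coh, list(trait_spec("t1", "continuous")), seed = 63)
  b <- simulate_phenome(coh, list(trait_spec("t2", "binary"),
                                  trait_spec("t1", "continuous")), seed = 63)
  expect_identical(a$phenome$t1, b$phenome$t1)
  expect_error(
    simulate_phenome(coh, list(trait_spec("x", "binary"),
                               trait_spec("x", "binary")), seed = 1),
    class = "mrphewas_config_error")
})

test_that("gwas_summarize recovers an identity regression and flags degeneracy", {
  pan <- simulate_panel(5, seed = 71)
  coh <- simulate_cohort(pan, 2000, seed = 72)
  y <- coh$dosages[, 3]
  res <- gwas_summarize(coh, y)
  expect_equal(res$beta_outcome[3], 1, tolerance = 1e-10)
  expect_lt(res$se_outcome[3], 1e-10)

  res_const <- gwas_summarize(coh, rep(1, coh$n))
  expect_true(all(is.na(res_const$beta_outcome)))
  expect_true(all(grepl("constant trait", res_const$note)))
  expect_equal(nrow(res_const), 5)  # flagged, not dropped
})

test_that("gwas_summarize is calibrated on a null trait", {
  pan <- simulate_panel(50, seed = 81)
  coh <- simulate_cohort(pan, 5000, seed = 82)
  set.seed(83)
  frac <- mean(gwas_summarize(coh, rnorm(coh$n))$pval_outcome < 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / 50)
  expect_lt(abs(frac - 0.05), band + 1e-9)
})

test_that("gwas_summarize matches lm/glm coefficient tests", {
  pan <- simulate_panel(8, seed = 91)
  coh <- simulate_cohort(pan, 3000, seed = 92)
  coh <- simulate_phenome(coh, list(
    trait_spec("yc", "continuous", beta_menarche = -0.2),
    trait_spec("yb", "binary", beta_menarche = -0.3, prevalence = 0.4)),
    seed = 93)
  cv <- default_covariates(coh)
  res <- gwas_summarize(coh, "yc", covariates = cv)
  ref <- lm(coh$phenome$yc ~ coh$dosages[, 4] + cv)
  expect_equal(res$beta_outcome[4], unname(coef(ref)[2]), tolerance = 1e-8)
  expect_equal(res$se_outcome[4],
               unname(summary(ref)$coefficients[2, 2]), tolerance = 1e-8)

  resb <- gwas_summarize(coh, "yb")
  refb <- glm(coh$phenome$yb ~ coh$dosages[, 4], family = binomial)
  expect_equal(resb$beta_outcome[4], unname(coef(refb)[2]), tolerance = 1e-6)
})
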