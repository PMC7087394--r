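# Harmonization, Wald ratios, IVW, Egger, median, mode, heterogeneity.

test_that("harmonize aligns swapped, complementary and palindromic rows", {
  ex <- data.frame(
    rsid = c("r1", "r2", "r3", "r4", "r5"),
    effect_allele = c("A", "C", "G", "A", "A"),
    other_allele  = c("G", "T", "A", "T", "T"),
    eaf = c(0.3, 0.4, 0.6, 0.5, 0.2),
    beta_exposure = c(-0.1, 0.2, -0.15, 0.1, -0.2),
    se_exposure = 0.02)
  ou <- data.frame(
    rsid = c("r1", "r2", "r3", "r4", "r5", "r9"),
    effect_allele = c("A", "T", "C", "A", "T", "A"),
    other_allele  = c("G", "C", "T", "T", "A", "C"),
    eaf = c(0.31, 0.61, 0.59, 0.5, 0.81, 0.5),
    beta_outcome = c(0.5, 0.3, 0.2, 0.4, 0.25, 1),
    se_outcome = 0.05)
  mri <- harmonize(ex, ou)
  # r1 aligned; r2 swapped alleles -> flipped; r3 complement strand aligned;
  # r4 palindromic ambiguous (eaf 0.5) -> dropped; r5 palindromic with clear
  # frequency -> flipped (outcome eaf 0.81 matches 1 - 0.2)
  expect_setequal(mri$rsid, c("r1", "r2", "r3", "r5"))
  expect_equal(mri$beta_out[mri$rsid == "r1"], 0.5)
  expect_equal(mri$beta_out[mri$rsid == "r2"], -0.3)
  expect_equal(mri$beta_out[mri$rsid == "r3"], 0.2)
  expect_true(mri$flipped[mri$rsid == "r2"])
  expect_equal(mri$beta_out[mri$rsid == "r5"], -0.25)
  dropped <- attr(mri, "dropped")
  expect_equal(dropped$rsid, "r4")
  expect_match(dropped$reason, "palindromic")
  expect_error(harmonize(ex, ou[ou$rsid == "r9", ]),
               class = "mrphewas_input_error")
})

test_that("wald_ratios computes the ratio and delta-method SE", {
  mri <- toy_mri(beta_exp = c(0.25, 0.1), se_exp = c(0.01, 0.01),
                 beta_out = c(0.5, 0), se_out = c(0.1, 0.08))
  wr <- wald_ratios(mri)
  expect_equal(wr$ratio, c(2, 0))
  expect_equal(wr$se, c(0.1 / 0.25, 0.08 / 0.1))

  expect_warning(wz <- wald_ratios(toy_mri(c(0.2, 0), c(0.01, 0.01),
                                           c(0.1, 0.1), c(0.05, 0.05))),
                 "zero exposure effect")
  expect_equal(nrow(wz), 1)

  # strong instruments: first- and second-order SEs agree within 5%
  mri2 <- toy_mri(beta_exp = 0.3, se_exp = 0.02, beta_out = 0.15,
                  se_out = 0.05)
  s1 <- wald_ratios(mri2, order = 1)$se
  s2 <- wald_ratios(mri2, order = 2)$se
  expect_lt(abs(s1 - s2) / s2, 0.05)
})

test_that("IVW matches hand-computed pooling and degenerate heterogeneity", {
  mri <- toy_mri(beta_exp = c(1, 1), se_exp = c(0.01, 0.01),
                 beta_out = c(0.2, 0.4), se_out = c(0.1, 0.2))
  f <- mr_ivw(mri, "fixed")
  expect_equal(f$beta, 0.24)
  expect_equal(f$se, 1 / sqrt(125))

  same <- toy_mri(beta_exp = rep(1, 3), se_exp = 0.01,
                  beta_out = rep(0.3, 3), se_out = 0.1)
  r <- mr_ivw(same, "random")
  expect_equal(r$beta, 0.3)
  expect_equal(r$Q, 0)
  expect_equal(r$I2, 0)
  expect_equal(r$tau2, 0)
  # tau2 = 0 => random equals fixed
  expect_equal(r$se, mr_ivw(same, "fixed")$se)

  expect_warning(one <- mr_ivw(toy_mri(1, 0.01, 0.2, 0.1), "random"),
                 "falling back")
  expect_equal(one$method, "ivw_fixed")
})

test_that("MR-Egger recovers an exact line and requires 3 variants", {
  mri <- toy_mri(beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
                 beta_out = c(0.05, 0.15, 0.25), se_out = 0.1)
  e <- mr_egger(mri)
  expect_equal(e$beta, 1, tolerance = 1e-10)
  expect_equal(e$intercept, -0.05, tolerance = 1e-10)
  expect_true(is.finite(e$se) && e$se > 0)
  expect_error(mr_egger(mri[1:2, ]), class = "mrphewas_method_error")
})

test_that("Egger with intercept constrained to zero reproduces fixed IVW", {
  # the through-origin WLS slope with weights 1/se_out^2 is algebraically
  # the fixed-effect IVW estimate; check on random inputs
  set.seed(7)
  for (i in 1:100) {
    k <- sample(3:20, 1)
    mri <- toy_mri(beta_exp = runif(k, 0.05, 0.4) * sample(c(-1, 1), k, TRUE),
                   se_exp = runif(k, 0.005, 0.02),
                   beta_out = rnorm(k, 0, 0.1),
                   se_out = runif(k, 0.02, 0.2))
    w <- 1 / mri$se_out^2
    slope0 <- sum(w * mri$beta_exp * mri$beta_out) / sum(w * mri$beta_exp^2)
    expect_equal(mr_ivw(mri, "fixed")$beta, slope0, tolerance = 1e-10)
  }
})

test_that("weighted median interpolates cumulative weight 0.5", {
  eq <- toy_mri(beta_exp = rep(1, 3), se_exp = 0.01,
                beta_out = c(1, 2, 3), se_out = rep(0.1, 3))
  expect_equal(mr_weighted_median(eq, 50, seed = 1)$beta, 2)

  # a variant with overwhelming weight dominates
  dom <- toy_mri(beta_exp = rep(1, 4), se_exp = 0.01,
                 beta_out = c(5, 1.0, 7, 9), se_out = c(1, 1e-4, 1, 1))
  expect_lt(abs(mr_weighted_median(dom, 50, seed = 1)$beta - 1.0), 0.01)
  expect_error(mr_weighted_median(eq[1:2, ], 50, seed = 1),
               class = "mrphewas_method_error")
})

test_that("mode estimators find the densest ratio cluster", {
  mri <- toy_mri(beta_exp = rep(1, 4), se_exp = 0.01,
                 beta_out = c(1, 1.01, 0.99, 5), se_out = rep(0.1, 4))
  m <- mr_mode(mri, bootstrap_reps = 50, seed = 2)
  expect_lt(abs(m$beta - 1), 0.15)

  const <- toy_mri(beta_exp = rep(1, 3), se_exp = 0.01,
                   beta_out = rep(0.7, 3), se_out = rep(0.1, 3))
  mc <- mr_mode(const, bootstrap_reps = 10, seed = 2)
  expect_equal(mc$beta, 0.7)
  expect_equal(mc$se, 0)

  mw <- mr_mode(mri, weighted = TRUE, bootstrap_reps = 50, seed = 2)
  expect_equal(mw$method, "weighted_mode")
  expect_lt(abs(mw$beta - 1), 0.15)
})

test_that("all two-sample estimators are scale equivariant in the outcome", {
  set.seed(11)
  mri <- sim_summary_mri(20, true_beta = -0.1, seed = 12)
  cc <- 3.7
  mri2 <- mri
  mri2$beta_out <- cc * mri$beta_out
  mri2$se_out <- cc * mri$se_out
  for (fn in list(function(x) mr_ivw(x, "fixed"),
                  function(x) mr_ivw(x, "random"),
                  mr_egger,
                  function(x) mr_weighted_median(x, 100, seed = 3),
                  function(x) mr_mode(x, bootstrap_reps = 100, seed = 3))) {
    a <- fn(mri); b <- fn(mri2)
    expect_equal(b$beta, cc * a$beta, tolerance = 1e-6)
    expect_equal(b$se, cc * a$se, tolerance = 0.25)  # bootstrap SEs are MC-noisy
  }
})

test_that("weighted median resists 40% invalid instruments better than IVW", {
  set.seed(13)
  hits_med <- 0; hits_ivw <- 0
  for (r in 1:40) {
    k <- 30
    pleio <- c(rep(0, 18), runif(12, 0.05, 0.15))  # 40% invalid, one-sided
    mri <- sim_summary_mri(k, true_beta = -0.1, seed = 1000 + r,
                           pleiotropy = pleio)
    wm <- mr_weighted_median(mri, 100, seed = r)
    iv <- mr_ivw(mri, "random")
    if (wm$ci_low <= -0.1 && -0.1 <= wm$ci_high) hits_med <- hits_med + 1
    if (iv$ci_low <= -0.1 && -0.1 <= iv$ci_high) hits_ivw <- hits_ivw + 1
  }
  expect_gt(hits_med, hits_ivw)
  expect_gt(hits_med, 20)
})

test_that("cohort heterogeneity Q matches the hand calculation", {
  two_same <- data.frame(beta = c(0.2, 0.2), se = c(0.1, 0.3))
  h <- cohort_heterogeneity(two_same)
  expect_equal(h$Q, 0)
  expect_equal(h$I2, 0)

  h2 <- cohort_heterogeneity(data.frame(beta = c(0, 0.6), se = c(0.1, 0.1)))
  expect_equal(h2$Q, 18)
  expect_equal(h2$p, pchisq(18, 1, lower.tail = FALSE))
  expect_error(cohort_heterogeneity(data.frame(beta = 1, se = 0.1)),
               class = "mrphewas_input_error")
})

test_that("flip_orientation negates slope and intercept and swaps the CI", {
  mri <- toy_mri(beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
                 beta_out = c(0.06, 0.11, 0.33), se_out = 0.1)
  e <- mr_egger(mri)
  f <- flip_orientation(e)
  expect_equal(f$beta, -e$beta)
  expect_equal(f$intercept, -e$intercept)
  expect_equal(f$ci_low, -e$ci_high)
  expect_equal(f$ci_high, -e$ci_low)
  expect_equal(f$pval, e$pval)
})
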