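# GRS construction, instrument strength, Steiger and proximity filtering.

test_that("compute_grs orients to the exposure-decreasing allele", {
  d <- matrix(0:2, 3, 1, dimnames = list(NULL, "rs1"))
  expect_equal(compute_grs(d, c(rs1 = -0.1)), c(0, 0.1, 0.2))
  # positive effect: the opposite allele is counted
  expect_equal(compute_grs(d, c(rs1 = 0.1)), c(0.2, 0.1, 0))
  expect_equal(compute_grs(d, c(rs1 = 0)), c(0, 0, 0))
})

test_that("compute_grs equals a brute-force oriented dot product", {
  set.seed(1)
  d <- matrix(sample(0:2, 12, TRUE), 4, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  w <- c(a = -0.2, b = 0.15, c = -0.05)
  manual <- sapply(1:4, function(i) {
    s <- 0
    for (j in names(w)) {
      dos <- if (w[j] > 0) 2 - d[i, j] else d[i, j]
      s <- s + abs(w[j]) * dos
    }
    s
  })
  expect_equal(compute_grs(d, w), unname(manual))
  expect_error(compute_grs(d, c(zz = 1)), class = "mrphewas_input_error")
})

test_that("compute_grs is invariant to effect-allele relabelling", {
  pan <- simulate_panel(12, seed = 5)
  coh <- simulate_cohort(pan, 500, seed = 6)
  s1 <- compute_grs(coh, pan)
  # relabel: swap alleles, flip beta and dosage
  pan2 <- pan
  pan2$beta_exposure <- -pan$beta_exposure
  d2 <- 2 - coh$dosages
  s2 <- compute_grs(d2, stats::setNames(pan2$beta_exposure, pan2$rsid))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("instrument_strength reports incremental R2 and partial F", {
  set.seed(2)
  x <- rnorm(5000)
  expect_equal(instrument_strength(x, x)$r_squared, 1, tolerance = 1e-12)

  y <- rnorm(5000)
  ns <- instrument_strength(x, y)
  expect_lt(ns$r_squared, 0.002)

  expect_warning(z <- instrument_strength(rep(1, 100), rnorm(100)),
                 "zero variance")
  expect_equal(z$r_squared, 0)

  # agreement with anova() partial F
  cv <- matrix(rnorm(5000 * 2), ncol = 2)
  e <- 0.3 * x + rnorm(5000)
  st <- instrument_strength(x, e, cv)
  f0 <- lm(e ~ cv); f1 <- lm(e ~ cv + x)
  expect_equal(st$f_statistic, anova(f0, f1)$F[2], tolerance = 1e-8)
  expect_equal(st$r_squared,
               summary(f1)$r.squared - summary(f0)$r.squared,
               tolerance = 1e-8)
})

test_that("the default panel delivers ~6.1% exposure variance explained", {
  pan <- simulate_panel(60, seed = 9)
  coh <- simulate_cohort(pan, 100000, seed = 10)
  st <- instrument_strength(compute_grs(coh, pan), coh$exposure,
                            default_covariates(coh))
  expect_gte(st$r_squared, 0.050)
  expect_lte(st$r_squared, 0.072)
})

test_that("steiger_filter excludes exactly the planted BMI-dominant variants", {
  pan <- simulate_panel(30, seed = 15)
  planted <- pan$rsid[1:5]
  # fixed, well-separated effects: planted variants have essentially no
  # exposure effect but a strong direct childhood-BMI effect that tracks
  # into adult BMI; the rest are solid exposure instruments
  pan$beta_exposure <- rep(c(-0.12, 0.12), 15)
  pan$beta_exposure[1:5] <- 0.002
  prm <- cohort_params(pleiotropy_rsids = planted, pleiotropy_beta = 1.2)
  coh <- simulate_cohort(pan, 50000, prm, seed = 16)
  vs <- steiger_filter(coh)
  expect_setequal(vs$excluded_rsids, planted)

  # brute-force agreement on every variant
  comp <- coh$adult_bmi
  excl_bf <- vapply(seq_len(nrow(pan)), function(j) {
    cor(coh$dosages[, j], comp)^2 > cor(coh$dosages[, j], coh$exposure)^2
  }, logical(1))
  expect_identical(sort(vs$excluded_rsids), sort(pan$rsid[excl_bf]))
  expect_setequal(c(vs$included_rsids, vs$excluded_rsids), pan$rsid)
  expect_error(steiger_filter(coh, competing_trait = "nope"),
               class = "mrphewas_input_error")
})

test_that("proximity_filter is inclusive at the window boundary", {
  pan <- data.frame(rsid = c("v1", "v2", "v3"), chrom = c(1, 1, 2),
                    pos = c(1000000L, 2000001L, 1500000L),
                    effect_allele = "A", other_allele = "G", eaf = 0.5,
                    beta_exposure = -0.1, se_exposure = 0.01)
  hits <- data.frame(chrom = 1, pos = 1500000L)
  vs <- proximity_filter(pan, hits)
  expect_equal(vs$excluded_rsids, "v1")        # distance exactly 500,000
  expect_false("v3" %in% vs$excluded_rsids)    # other chromosome, same reach
  expect_false("v2" %in% vs$excluded_rsids)    # 500,001 bp away
  # rsid match excludes regardless of position
  vs2 <- proximity_filter(pan, data.frame(rsid = "v3", chrom = 9, pos = 1L))
  expect_equal(vs2$excluded_rsids, "v3")
  # empty hit list excludes nothing
  expect_length(proximity_filter(pan, NULL)$excluded_rsids, 0)
})

test_that("proximity_filter matches an exhaustive pairwise scan", {
  set.seed(33)
  for (rep in 1:20) {
    pan <- simulate_panel(15, seed = rep, allow_close = TRUE)
    hits <- data.frame(chrom = sample(1:22, 4, TRUE),
                       pos = sample.int(3e7, 4))
    vs <- proximity_filter(pan, hits)
    bf <- vapply(seq_len(nrow(pan)), function(i)
      any(hits$chrom == pan$chrom[i] & abs(hits$pos - pan$pos[i]) <= 5e5),
      logical(1))
    expect_setequal(vs$excluded_rsids, pan$rsid[bf])
  }
})

test_that("build_instrument_sets partitions the panel four ways", {
  pan <- simulate_panel(40, seed = 44)
  child <- pan[1:3, c("rsid", "chrom", "pos")]
  adult <- pan[3:10, c("rsid", "chrom", "pos")]
  coh <- simulate_cohort(pan, 5000, seed = 45)
  sets <- build_instrument_sets(pan, coh, child, adult)
  expect_named(sets, c("all", "steiger", "child_bmi", "bmi"))
  expect_length(sets$all$excluded_rsids, 0)
  expect_setequal(sets$child_bmi$excluded_rsids, pan$rsid[1:3])
  expect_setequal(sets$bmi$excluded_rsids, pan$rsid[1:10])
  for (s in sets) {
    expect_setequal(c(s$included_rsids, s$excluded_rsids), pan$rsid)
    expect_length(intersect(s$included_rsids, s$excluded_rsids), 0)
  }
  # empty hits and no cohort: all four sets identical
  sets0 <- build_instrument_sets(pan)
  expect_true(all(vapply(sets0, function(s)
    length(s$excluded_rsids) == 0, logical(1))))
})

test_that("filtering never raises the score R2 beyond sampling noise", {
  pan <- simulate_panel(50, seed = 55)
  coh <- simulate_cohort(pan, 50000, seed = 56)
  full <- instrument_strength(compute_grs(coh, pan), coh$exposure)$r_squared
  sub <- apply_variant_set(pan, proximity_filter(
    pan, pan[1:10, c("rsid", "chrom", "pos")]))
  reduced <- instrument_strength(compute_grs(coh, sub),
                                 coh$exposure)$r_squared
  expect_lt(reduced, full + 0.005)
})
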