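# mrphewas

Hypothesis-free Mendelian randomization phenome scans with a genetic
risk score instrument, plus the complete follow-up estimator suite.

## What it is for

Mendelian randomization (MR) treats genetic variants as instrumental
variables for a modifiable exposure: because alleles are fixed at
conception, an association between an exposure-predicting genetic risk
score (GRS) and an outcome supports a causal effect of the exposure,
provided the variants act on the outcome only through it. An MR phenome-
wide association scan (MR-pheWAS) screens one GRS against thousands of
traits at once and then interrogates the hits with estimators that relax
the no-pleiotropy assumption in different ways.

`mrphewas` implements that workflow for a continuous exposure modelled on
age at menarche (mean 12.9 y, SD 1.6 y; a ~360-variant score explaining
~6% of its variance), for biostatisticians and genetic epidemiologists
who want a tested, reproducible pipeline they can exercise end to end on
synthetic cohorts with known causal structure:

* **Synthetic cohorts** (`simulate_panel`, `simulate_cohort`,
  `simulate_phenome`, `gwas_summarize`): Hardy–Weinberg genotypes,
  exposure with exact target variance explained, horizontal pleiotropy
  into childhood BMI, a vertical exposure → adult BMI path, and a phenome
  of continuous/binary/ordered/unordered traits with configurable causal
  effects and BMI mediation.
* **Instruments** (`compute_grs`, `instrument_strength`,
  `steiger_filter`, `proximity_filter`, `build_instrument_sets`): the
  exposure-decreasing-allele weighted score and the four standard
  instrument sets (all variants; Steiger-filtered; childhood-BMI hits
  excluded; all BMI hits excluded, 500 kb inclusive window).
* **Phenome scan** (`run_phewas`, `scan_trait`,
  `inverse_normal_transform`, `fdr_threshold`, `bonferroni_threshold`,
  `qq_data`): rule-based trait typing, inverse-normal transformation,
  regression dispatch (linear / logistic / ordered logistic / multinomial
  LRT), and the rank-threshold FDR rule `P_t = 0.05 · rank / n` alongside
  Bonferroni.
* **MR estimators** (`harmonize`, `wald_ratios`, `mr_ivw`, `mr_egger`,
  `mr_weighted_median`, `mr_mode`, `mr_presso`, `one_sample_mr`,
  `multivariable_mr`, `cohort_heterogeneity`): the two-sample suite with
  pleiotropy diagnostics, one-sample two-stage regression with bootstrap
  SEs, and multivariable MR for mediator adjustment.
* **Power** (`mde_continuous`, `mde_binary`, `power_at_effect`,
  `power_table`): closed-form minimal detectable effects,
  `(z_{1-α/2} + z_{pow}) / √(n·R²)`, and their exact inverse.

`run_pipeline(run_config(seed = ...))` chains all stages and writes
commented TSVs (panel, instrument sets, per-set scan results and
threshold reports, QQ data, MR estimates, MR-PRESSO summary, power
table).

## Worked example

```r
library(mrphewas)

pan <- simulate_panel(60, seed = 1)          # 60 instruments, 6.1% R2 target
coh <- simulate_cohort(pan, 20000, seed = 2) # biobank-like cohort
coh <- simulate_phenome(coh, list(
  trait_spec("fev1", "continuous", beta_menarche = 0.15),
  trait_spec("t2d", "binary", beta_menarche = -0.2, prevalence = 0.1),
  trait_spec("null_trait", "continuous")), seed = 3)

score <- compute_grs(coh, pan)
instrument_strength(score, coh$exposure, default_covariates(coh))
#> Instrument strength: R^2 = 0.0632 (6.3%), F = 1348.0, n = 20000

ph <- run_phewas(coh, score)
ph$thresholds
#> 3 tests: FDR threshold 0.0333 (rank 2, 2 discoveries); Bonferroni 0.0167 (2 discoveries)
```

The strength line says the score explains 6.3% of exposure variance in
this draw (the generator targets 6.1% analytically); the threshold report
says two of the three traits — the two with planted effects — pass both
the 5% FDR rank threshold and Bonferroni, while the null trait does not.

Two-sample follow-up on summary statistics:

```r
coh2 <- simulate_cohort(pan, 20000, seed = 4)          # independent sample
coh2 <- simulate_phenome(coh2, list(
  trait_spec("fev1", "continuous", beta_menarche = 0.15)), seed = 5)
es  <- gwas_summarize(coh, "exposure")
pan_hat <- pan
pan_hat$beta_exposure <- es$beta_outcome; pan_hat$se_exposure <- es$se_outcome
mri <- harmonize(pan_hat, gwas_summarize(coh2, "fev1"))
flip_orientation(mr_ivw(mri))   # per year DECREASE in the exposure
#> MR estimate [ivw_random]: beta = -0.1354 (se 0.0205, 95% CI -0.1756 to -0.0952), p = 4.15e-11, 58 SNPs
#>   Q = 65.41 (p = 0.208), I2 = 12.9%, tau2 = 0.002803
```

The trait was simulated with a causal effect of +0.15 per year of
exposure, so the per-year-*decrease* IVW estimate of −0.135 (CI −0.176 to
−0.095) recovers it; two palindromic variants were dropped in
harmonization (58 of 60 SNPs), and the heterogeneity statistics show no
excess dispersion beyond sampling noise.

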