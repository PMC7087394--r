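---
title: "Methods: genetic-risk-score phenome scans and the MR estimator suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic-risk-score phenome scans and the MR estimator suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrphewas)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure: because alleles are allocated at
conception, an association between an exposure-predicting genetic score
and an outcome is evidence of a causal effect of the exposure, provided
the instruments affect the outcome only through the exposure. A
phenome-wide MR scan (MR-pheWAS) turns this into a hypothesis-free screen:
one weighted genetic risk score (GRS) is tested against thousands of
traits, and discoveries are followed up with the full battery of
sensitivity estimators that relax the exclusion-restriction assumption in
different ways.

`mrphewas` implements this design end to end for a continuous exposure
modelled on age at menarche (years): a synthetic cohort generator with
explicit pleiotropy structure, GRS construction with instrument-set
filtering, a rule-based phenome scan with FDR/Bonferroni thresholding, the
two-sample and one-sample estimator suite, and analytic power
calculations. Because individual-level biobank data are access-controlled,
the generator is a first-class module: it provides cohorts whose causal
structure is known exactly, so every downstream procedure can be verified
by parameter recovery rather than by comparison with unavailable data.

## The generative model

The simulator encodes the causal diagram the analysis assumes:

* `m` biallelic variants with effect-allele frequencies
  $p_j \sim U(f_{lo}, f_{hi})$, dosages $d_j \sim \text{Binomial}(2, p_j)$
  under Hardy–Weinberg and linkage equilibrium. The instruments represent
  independent association signals, so the no-LD assumption is faithful to
  how such panels are built and keeps the variance arithmetic analytic.
* Exposure $X = \mu_X + \sum_j \beta_j (d_j - 2p_j) + c_U U + \epsilon$,
  with $U \sim N(0,1)$ a latent confounder and the residual variance
  chosen so $\mathrm{sd}(X)$ equals the configured total (default
  $\mu_X = 12.9$, $\mathrm{sd} = 1.6$ years, matching the reported
  biobank distribution of age at menarche). Effect sizes are rescaled so
  the panel's analytic variance explained
  $\sum_j 2p_j(1-p_j)\beta_j^2 / \sigma_X^2$ hits the configured target
  exactly (default 6.1%, the reported strength of a ~360-SNP score).
* Horizontal pleiotropy: a designated variant subset has direct
  per-allele effects on childhood BMI.
* Vertical pleiotropy: adult BMI
  $B = \mu_B + \lambda (B_{child} - \mu_{Bc}) + \gamma (X - \mu_X) + c_U U
  + \epsilon_B$, so the exposure feeds adult BMI (default $\gamma = -0.35$
  kg/m² per year — earlier menarche, higher adult BMI — a magnitude in
  line with the observational literature; $\lambda = 0.9$ tracking from
  childhood).
* Phenome traits are built from a latent variable
  $L = \beta\,[(1-w)(X - \bar X) + w(B - \bar B)] + \sum_j d_j \gamma_j +
  \epsilon$: $w$ routes a fraction of the causal effect through the adult
  BMI mediator, and the $\gamma_j$ are direct (horizontally pleiotropic)
  variant effects. Binary and ordered traits threshold $L$ at cut-points
  solved from the requested marginal frequencies; unordered traits use a
  multinomial logit with intercepts $\log p_\ell$ and centred level
  slopes, so a null latent reproduces the requested margins exactly.

One global seed expands into named substreams (genotypes, phenotypes, one
per trait, one per bootstrap), so adding a trait never perturbs the
genotype draws and every stage is a pure function of (inputs, parameters,
seed).

What the generator does *not* emulate: linkage disequilibrium, imputation
uncertainty, X-chromosome dosage, relatedness, selection into the cohort,
and real phenome measurement error. Passing tests therefore demonstrate
that the procedures are implemented correctly and are calibrated under
the assumed model — not that the assumptions hold in any particular real
cohort.

## Instrument sets and the score

`compute_grs()` orients every variant to its exposure-*decreasing* allele
(dosage flipped to $2-d$ when the effect allele raises the exposure) and
sums $|\beta_j|$-weighted oriented dosages, so a higher score always means
a genetically earlier menarche. Four instrument sets mirror the standard
sensitivity ladder:

| label | rule |
|---|---|
| `all` | every panel variant |
| `steiger` | drop variants whose squared dosage–trait correlation is strictly larger for the competing trait (default adult BMI) than for the exposure |
| `child_bmi` | drop variants within 500 kb of (or named in) a childhood-BMI hit list |
| `bmi` | as above with childhood and adult hit lists combined |

Two boundary decisions are deliberate and configurable: the proximity
window is *inclusive* at exactly 500,000 bp (a variant "within" the window
is excluded), and a Steiger tie is *kept* (exclusion requires strictly
more competing-trait variance). Per-variant $r^2$ is computed from
individual-level data, as the scan itself has individual data available.

Instrument strength is reported as incremental $R^2$ of the score over a
covariate-only model and the partial F of the score term,
$F = (RSS_0 - RSS_1)/(RSS_1/(n-p-2))$. We report this partial F with its
formula because published $R^2$/F pairs for large biobank scores are not
always mutually consistent, and the partial F is the quantity with an
unambiguous definition.

## The phenome scan

Trait typing follows a compact rule set (declared kind wins; two distinct
values → binary; integer codes with ≤ 20 distinct values → ordered;
non-numeric → unordered; else continuous). The distinct-value cutoff of
20, the binary case floor of 50, and the rank offset of the inverse-normal
transform (Blom's 3/8) are all exposed in `scan_options()`; these are
conventional defaults rather than values dictated by any single source,
and each decision is logged per trait in the scan output.

Continuous traits are inverse-normal rank transformed,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ with average ranks for ties,
then fitted by linear regression; binary traits by logistic, ordered by
proportional-odds logistic (`MASS::polr`), unordered by multinomial
logistic (`nnet::multinom`) with the most frequent level as reference and
only a likelihood-ratio p-value on $L-1$ degrees of freedom (no single
slope is meaningful there). Single-coefficient p-values use the
large-sample normal, appropriate at biobank scale. Non-convergence or
separation produces a flagged row, never a silent drop.

Multiplicity control is the rank-threshold FDR rule: sort p-values,
find the largest rank $r$ with $p_{(r)} < 0.05\,r/n$, and declare
everything below $P_t = 0.05\,r/n$ a discovery. The strict `<` is
implemented exactly as the procedure is stated for phenome scans; it can
differ from step-up Benjamini–Hochberg (which uses $\le$) only when a
p-value ties its rank threshold to machine precision, and ties at the
boundary are non-discoveries here. With $n = 17{,}893$ tests this
arithmetic reproduces the published thresholds ($P_t = 1.73\times10^{-3}$
at rank 619, Bonferroni $2.79\times10^{-6}$), which the acceptance script
recomputes.

## The estimator suite

All estimators consume a harmonized table of per-variant effect pairs.
Harmonization aligns outcome rows to the exposure's effect allele,
resolving swapped alleles (sign flip) and strand flips (complement);
palindromic A/T and C/G variants whose minor-allele frequency is within
0.08 of 0.5 are ambiguous and dropped, others are oriented by frequency.

* **Wald ratio**: $r_j = \beta_{out,j}/\beta_{exp,j}$ with first-order
  delta SE $|se_{out,j}/\beta_{exp,j}|$. Exposure uncertainty is ignored
  by default — standard for strong instruments, and a second-order SE is
  available behind a flag (the two agree within 5% once
  $|\beta_{exp}/se_{exp}| > 10$).
* **IVW**, fixed and random effects. Random effects uses the
  DerSimonian–Laird moment $\tau^2$; with $\tau^2 = 0$ it collapses to
  fixed effects exactly, a property the tests assert.
* **MR-Egger**: WLS with intercept, weights $1/se_{out}^2$, variants
  oriented to non-negative exposure effects. The intercept estimates the
  average directional pleiotropy under InSIDE. Overdispersion is handled
  by a multiplicative scale floored at 1, with t-based p-values on $k-2$
  df.
* **Weighted median**: interpolation of the ordered ratios at cumulative
  normalized inverse-variance weight 0.5; robust while valid instruments
  hold a weight majority.
* **Mode-based** (simple/weighted): normal-kernel density over the
  ratios, bandwidth $\phi \times 0.9\,\min(sd, mad)\,k^{-1/5}$
  (modified Silverman, $\phi = 1$ default), argmax on a grid spanning the
  ratios ± 3 bandwidths (10,000 points; the FFT density makes this cheap).
* **MR-PRESSO**: leave-one-out IVW residual sum of squares with a
  parametric null ($\beta_{out}^* \sim N(\hat\beta_{out}, se_{out}^2)$),
  per-variant outlier p-values Bonferroni-corrected across variants, an
  outlier-pruned IVW estimate, and a distortion test against random
  removal of equally many variants. The adjusted estimate is recommended
  only when global and distortion p-values are both below 0.05 — the
  published decision rule.
* **One-sample MR**: linear first stage, linear/logistic second stage on
  the predicted exposure, nonparametric bootstrap over individuals
  re-running *both* stages (resampling only the second stage would
  understate the uncertainty; replicate count is configurable, default
  1000).
* **Multivariable MR**: each exposure regressed on all scores jointly,
  outcome on all predicted exposures; reports direct effects, e.g. of the
  exposure net of adult BMI. Near-collinear scores (|r| > 0.999) abort
  with the offending pair named.

Median, mode and PRESSO standard errors come from parametric bootstrap
over the summary statistics with mandatory seeds. Estimators return
effects per unit *increase* of the exposure; `flip_orientation()` applies
the per-year-*decrease* convention used in forest plots, at the reporting
layer only, so internal arithmetic never double-flips.

## Power

For a GRS explaining a fraction $R^2_{XZ}$ of exposure variance, the
two-stage least-squares test statistic has noncentrality
$\sqrt{n R^2_{XZ}}\,\beta$ (effects in SD outcome per SD exposure), giving
the minimal detectable effect
$(z_{1-\alpha/2} + z_{pow})/\sqrt{n R^2_{XZ}}$, with the binary-outcome
version scaling the effective sample size by the case-control variance
factor $p(1-p)$. `power_at_effect()` inverts the formula; the round trip
is exact to $10^{-10}$ and both directions are strictly monotone in every
argument. This is the standard asymptotic used by MR power calculators;
the formula is stated here (and in the output metadata) because published
post hoc power numbers often omit their exact inputs.

## Numerical and design choices

* Degenerate inputs are defined, not fatal: zero-variance scores give
  $R^2 = 0$ with a warning; constant traits are flagged rows; identical
  ratios give the common value with zero SE; a single variant falls back
  from random- to fixed-effect IVW with a warning.
* `fdr_threshold()` reports threshold 0 when no rank passes, so "no
  discoveries" is representable without a special case.
* QQ data flag p-values at the double floor (≈ 2.2e-308) rather than
  taking log of zero.
* The test suite and examples use deliberately scaled problem sizes —
  e.g. 200-replicate coverage runs at 50,000 individuals per sample and
  two-sample panels of 50 variants, 500-replicate type-I runs at 20,000
  individuals — chosen so the full distributional checks (coverage in
  [0.90, 0.99], type-I inside the binomial 95% band, KS uniformity of the
  PRESSO global p) have useful Monte-Carlo resolution while the suite
  stays fast enough to run routinely.
* Bootstrap replicate counts in tests (100–200) are smaller than the
  production default (1000); they enter only through standard-error
  estimates whose Monte-Carlo error is second order in the assertions
  made.

## A worked example

```{r example, eval = FALSE}
pan <- simulate_panel(60, seed = 1)
coh <- simulate_cohort(pan, 20000, seed = 2)
coh <- simulate_phenome(coh, list(
  trait_spec("fev1", "continuous", beta_menarche = 0.15, noise_sd = 1),
  trait_spec("neuroticism", "ordered", beta_menarche = -0.1, levels = 5),
  trait_spec("null_trait", "continuous")), seed = 3)
score <- compute_grs(coh, pan)
instrument_strength(score, coh$exposure, default_covariates(coh))
ph <- run_phewas(coh, score)
ph$thresholds
```

## Known limitations

* No LD-aware modelling anywhere: panels are treated as independent
  signals, and external hit lists are taken as given (no clumping).
* Trait typing is the compact rule set above, not a re-implementation of
  any biobank field-coding system (no data-coding reassignment or
  instance/array collapsing).
* No nonlinear MR: those methods need one-sample designs at sample sizes
  outside this package's scope, and threshold placement remains
  unsettled.
* The multinomial branch reports only an LRT p-value; effect direction
  for unordered traits must come from follow-up models.
* MR-PRESSO's outlier test inherits the usual discreteness of simulation
  p-values at small `n_sim`; use 1000+ simulations for reporting.
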