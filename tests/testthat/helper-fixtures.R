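# Shared fixtures, built in code at test time.

# A hand-sized mr_input table with known values.
toy_mri <- function(beta_exp, se_exp, beta_out, se_out,
                    rsid = sprintf("rs%d", seq_along(beta_exp))) {
  out <- data.frame(rsid = rsid, beta_exp = beta_exp, se_exp = se_exp,
                    beta_out = beta_out, se_out = se_out,
                    palindromic = FALSE, flipped = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_input", "data.frame")
  out
}

# Summary-level two-sample draw: per-variant effect estimates sampled from
# their asymptotic normal laws. Fast route for estimator property tests;
# individual-level generation is exercised separately.
sim_summary_mri <- function(k, true_beta, seed, n_exp = 5e4, n_out = 5e4,
                            pleiotropy = rep(0, k), exposure_sd = 1.6,
                            outcome_sd = 1) {
  set.seed(seed)
  eaf <- runif(k, 0.1, 0.9)
  # effect magnitudes bounded away from zero: the panel emulates
  # genome-wide-significant instruments, not null variants
  beta_exp_true <- runif(k, 0.05, 0.15) * sample(c(-1, 1), k, TRUE)
  se_exp <- exposure_sd / sqrt(2 * eaf * (1 - eaf) * n_exp)
  se_out <- outcome_sd / sqrt(2 * eaf * (1 - eaf) * n_out)
  toy_mri(beta_exp = rnorm(k, beta_exp_true, se_exp),
          se_exp = se_exp,
          beta_out = rnorm(k, true_beta * beta_exp_true + pleiotropy, se_out),
          se_out = se_out)
}

# Individual-level two-sample pair: exposure cohort + outcome cohort carrying
# one continuous trait with the given causal effect of the exposure.
sim_two_sample <- function(m = 50, n = 5e4, true_beta = -0.10, seed = 1,
                           trait_noise = 1) {
  pan <- simulate_panel(m, seed = seed)
  coh_e <- simulate_cohort(pan, n, seed = seed * 2 + 1)
  coh_o <- simulate_cohort(pan, n, seed = seed * 2 + 2)
  coh_o <- simulate_phenome(
    coh_o, list(trait_spec("y", "continuous", beta_menarche = true_beta,
                           noise_sd = trait_noise)),
    seed = seed * 2 + 3)
  es <- gwas_summarize(coh_e, "exposure")
  pan_hat <- pan
  pan_hat$beta_exposure <- es$beta_outcome
  pan_hat$se_exposure <- es$se_outcome
  os <- gwas_summarize(coh_o, "y")
  harmonize(pan_hat, os)
}

# Brute-force FDR oracle: scan every rank explicitly.
brute_fdr <- function(p, q = 0.05) {
  n <- length(p)
  ps <- sort(p)
  rank <- 0L
  for (r in seq_len(n)) if (ps[r] < q * r / n) rank <- r
  threshold <- if (rank > 0) q * rank / n else 0
  list(threshold = threshold, rank = rank, discoveries = p < threshold)
}
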