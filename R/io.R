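# TSV I/O and the end-to-end pipeline. All tables are tab-separated UTF-8
# with '.' decimal and 'NA' for missing; every written file starts with
# comment lines recording the package version, a config hash and the seed.

tsv_header_lines <- function(seed = NA, config_hash = NA) {
  ver <- as.character(utils::packageVersion("mrphewas"))
  c(sprintf("# mrphewas %s", ver),
    sprintf("# config_hash: %s", config_hash),
    sprintf("# seed: %s", seed))
}

write_tsv <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(tsv_header_lines(seed, config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # identify the run by its parameters, not its location
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Read a variant weight table
#'
#' Expects a TSV with header columns \code{rsid, chrom, pos, effect_allele,
#' other_allele, eaf, beta, se} and optionally \code{pval} and \code{n}
#' (GWAS-summary-statistic layout). Rows are validated: duplicate rsids,
#' frequencies outside (0,1), non-positive standard errors and identical
#' alleles are rejected with the offending row named.
#'
#' @param path Path to the TSV file.
#' @return A \code{variant_panel}.
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  raw <- read_tsv(path)
  need <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort_input(paste0("weight table is missing column(s): ",
                       paste(miss, collapse = ", ")))
  if (anyDuplicated(raw$rsid)) {
    dup <- unique(raw$rsid[duplicated(raw$rsid)])
    abort_input(paste0("duplicate rsid(s): ", paste(dup, collapse = ", ")))
  }
  bad <- which(raw$eaf <= 0 | raw$eaf >= 1)
  if (length(bad))
    abort_input(sprintf("eaf out of (0,1) at row %d (rsid %s)",
                        bad[1], raw$rsid[bad[1]]))
  bad <- which(raw$se <= 0)
  if (length(bad))
    abort_input(sprintf("se must be > 0 at row %d (rsid %s)",
                        bad[1], raw$rsid[bad[1]]))
  bad <- which(raw$effect_allele == raw$other_allele)
  if (length(bad))
    abort_input(sprintf("identical alleles at row %d (rsid %s)",
                        bad[1], raw$rsid[bad[1]]))
  panel <- data.frame(rsid = raw$rsid, chrom = raw$chrom, pos = raw$pos,
                      effect_allele = raw$effect_allele,
                      other_allele = raw$other_allele, eaf = raw$eaf,
                      beta_exposure = raw$beta, se_exposure = raw$se,
                      pval_exposure = raw$pval %||%
                        2 * stats::pnorm(-abs(raw$beta / raw$se)),
                      stringsAsFactors = FALSE)
  class(panel) <- c("variant_panel", "data.frame")
  validate_panel(panel)
  panel
}

#' Write a variant panel as a weight-table TSV
#' @param panel A \code{variant_panel}.
#' @param path Output path.
#' @param seed Seed recorded in the header comment.
#' @return The path, invisibly.
#' @export
write_weight_table <- function(panel, path, seed = NA) {
  df <- data.frame(rsid = panel$rsid, chrom = panel$chrom, pos = panel$pos,
                   effect_allele = panel$effect_allele,
                   other_allele = panel$other_allele, eaf = panel$eaf,
                   beta = panel$beta_exposure, se = panel$se_exposure,
                   pval = panel$pval_exposure)
  write_tsv(df, path, seed = seed)
}

#' Write per-variant outcome summary statistics
#' @param stats A \code{summary_stats} table.
#' @param path Output path.
#' @param seed Seed recorded in the header comment.
#' @return The path, invisibly.
#' @export
write_summary_stats <- function(stats, path, seed = NA) {
  df <- stats
  df$n <- attr(stats, "sample_size") %||% NA
  write_tsv(df, path, seed = seed)
}

#' Read outcome summary statistics written by \code{write_summary_stats}
#' @param path Path to the TSV.
#' @return A \code{summary_stats} data.frame.
#' @export
read_summary_stats <- function(path) {
  df <- read_tsv(path)
  attr(df, "sample_size") <- df$n[1]
  df$n <- NULL
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Configuration for the end-to-end pipeline
#'
#' @param seed Mandatory integer seed; all stages derive substreams from it.
#' @param n_individuals,n_variants Cohort and panel sizes.
#' @param n_traits Number of phenome traits to simulate (a mix of
#'   continuous, binary, ordered and unordered, a fraction carrying true
#'   exposure effects).
#' @param signal_fraction Fraction of traits given a true causal effect.
#' @param instrument_sets Instrument-set labels to scan.
#' @param params \code{\link{cohort_params}} for the generator.
#' @param scan_opts \code{\link{scan_options}}.
#' @param followup_traits Continuous phenome traits taken to two-sample MR
#'   follow-up (NULL = first signal trait).
#' @param bootstrap_reps,presso_sims Replicates for the follow-up methods.
#' @param out_dir Output directory.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(seed, n_individuals = 5000, n_variants = 60,
                       n_traits = 150, signal_fraction = 0.1,
                       instrument_sets = c("all", "steiger", "child_bmi",
                                           "bmi"),
                       params = cohort_params(),
                       scan_opts = scan_options(),
                       followup_traits = NULL,
                       bootstrap_reps = 200, presso_sims = 500,
                       out_dir = tempfile("mrphewas_run_")) {
  if (missing(seed)) abort_input("`seed` is mandatory")
  structure(as.list(environment()), class = "run_config")
}

default_trait_specs <- function(config) {
  n <- config$n_traits
  kinds <- rep(c("continuous", "binary", "ordered", "unordered"),
               length.out = n)
  signal <- seq_len(n) <= ceiling(config$signal_fraction * n)
  lapply(seq_len(n), function(i) {
    trait_spec(sprintf("trait_%03d", i), kind = kinds[i],
               beta_menarche = if (signal[i]) -0.3 else 0,
               noise_sd = 1,
               prevalence = if (kinds[i] == "binary") 0.3 else NULL,
               levels = if (kinds[i] %in% c("ordered", "unordered")) 3 else NULL,
               category = if (signal[i]) "signal" else "null")
  })
}

#' Run the full MR-pheWAS pipeline on synthetic data
#'
#' Simulates a variant panel, cohort and phenome; builds the four
#' instrument sets (full, Steiger-filtered, childhood-BMI-excluded,
#' any-BMI-excluded) with a planted childhood-BMI pleiotropy subset; scans
#' the phenome with each instrument set; runs the two-sample estimator
#' suite plus MR-PRESSO on the follow-up traits; and writes a power table.
#' All tables land in \code{config$out_dir} as commented TSVs; rerunning
#' the same config reproduces them bit for bit.
#'
#' @param config A \code{\link{run_config}}.
#' @return The output directory, invisibly; the full result list as
#'   attribute \code{"results"}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    abort_input("`config` must be created by run_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- config_hash(config)
  seed <- config$seed
  log_msg <- function(...) message(sprintf(...))

  log_msg("[panel] simulating %d variants", config$n_variants)
  panel <- simulate_panel(config$n_variants, seed = seed)
  n_pleio <- max(1L, round(0.05 * config$n_variants))
  pleio_rsids <- panel$rsid[seq_len(n_pleio)]
  params <- config$params
  params$pleiotropy_rsids <- pleio_rsids
  write_weight_table(panel, file.path(config$out_dir, "panel.tsv"), seed)

  log_msg("[cohort] simulating %d individuals", config$n_individuals)
  cohort <- simulate_cohort(panel, config$n_individuals, params, seed = seed)
  specs <- default_trait_specs(config)
  cohort <- simulate_phenome(cohort, specs, seed = seed)

  child_hits <- panel[panel$rsid %in% pleio_rsids, c("rsid", "chrom", "pos")]
  sets <- build_instrument_sets(panel, cohort, child_hits = child_hits)
  sets <- sets[config$instrument_sets]
  set_tab <- do.call(rbind, lapply(sets, function(s)
    data.frame(label = s$label,
               rsid = c(s$included_rsids, s$excluded_rsids),
               excluded = c(rep(FALSE, length(s$included_rsids)),
                            rep(TRUE, length(s$excluded_rsids))),
               reason = c(rep("", length(s$included_rsids)),
                          unname(s$reason)))))
  write_tsv(set_tab, file.path(config$out_dir, "instrument_sets.tsv"),
            seed, ch)

  covars <- default_covariates(cohort)
  scan_results <- list()
  for (lab in names(sets)) {
    sub <- apply_variant_set(panel, sets[[lab]])
    score <- compute_grs(cohort, sub)
    strength <- instrument_strength(score, cohort$exposure, covars)
    log_msg("[phewas:%s] %d variants, R2 = %.3f", lab, nrow(sub),
            strength$r_squared)
    ph <- run_phewas(cohort, score, covariates = covars,
                     opts = config$scan_opts)
    scan_results[[lab]] <- list(phewas = ph, strength = strength,
                                score = score)
    write_tsv(ph$results,
              file.path(config$out_dir, sprintf("phewas_%s.tsv", lab)),
              seed, ch)
    thr <- ph$thresholds
    write_tsv(data.frame(key = names(unclass(thr)),
                         value = unlist(unclass(thr))),
              file.path(config$out_dir, sprintf("thresholds_%s.tsv", lab)),
              seed, ch)
    qq <- qq_data(ph$results$pval[!is.na(ph$results$pval)])
    write_tsv(qq, file.path(config$out_dir, sprintf("qq_%s.tsv", lab)),
              seed, ch)
  }

  # two-sample follow-up on an independent cohort
  followup <- config$followup_traits %||%
    names(Filter(function(s) s$kind == "continuous" && s$beta_menarche != 0,
                 cohort$trait_specs))[1]
  mr_rows <- list()
  if (length(followup) && !is.na(followup)) {
    log_msg("[mr] follow-up on %s", paste(followup, collapse = ", "))
    cohort2 <- simulate_cohort(panel, config$n_individuals, params,
                               seed = seed + 1)
    cohort2 <- simulate_phenome(cohort2, specs, seed = seed + 1)
    for (tr in followup) {
      out_stats <- gwas_summarize(cohort2, tr,
                                  covariates = default_covariates(cohort2))
      mri <- harmonize(panel, out_stats)
      ests <- list(
        mr_ivw(mri, "random"),
        mr_egger(mri),
        mr_weighted_median(mri, config$bootstrap_reps, seed),
        mr_mode(mri, weighted = FALSE,
                bootstrap_reps = config$bootstrap_reps, seed = seed),
        mr_mode(mri, weighted = TRUE,
                bootstrap_reps = config$bootstrap_reps, seed = seed)
      )
      ests <- lapply(ests, flip_orientation)
      mr_rows[[tr]] <- do.call(rbind, lapply(ests, function(e)
        data.frame(trait = tr, method = e$method, beta = e$beta, se = e$se,
                   ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
                   n_snps = e$n_snps)))
      pres <- mr_presso(mri, n_sim = config$presso_sims, seed = seed)
      write_tsv(data.frame(trait = tr, global_rss = pres$global_rss,
                           global_p = pres$global_p,
                           n_outliers = length(pres$outliers),
                           distortion_p = pres$distortion_p,
                           use_adjusted = pres$use_adjusted),
                file.path(config$out_dir, sprintf("presso_%s.tsv", tr)),
                seed, ch)
    }
    write_tsv(do.call(rbind, mr_rows),
              file.path(config$out_dir, "mr_estimates.tsv"), seed, ch)
  }

  designs <- data.frame(
    cohort = c("replication_A", "replication_B", "replication_binary"),
    n = c(22990, 60552, 5953), r2 = c(0.05, 0.05, 0.076),
    case_fraction = c(NA, NA, 0.1))
  write_tsv(power_table(designs),
            file.path(config$out_dir, "power.tsv"), seed, ch)

  writeLines(c(tsv_header_lines(seed, ch), deparse(config)),
             file.path(config$out_dir, "config.txt"))
  res <- list(panel = panel, cohort = cohort, sets = sets,
              scans = scan_results, mr = mr_rows)
  out <- config$out_dir
  attr(out, "results") <- res
  invisible(out)
}
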