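# Internal helpers shared across modules.

#' Derive a per-stage sub-seed from one global seed
#'
#' Expands a single user-supplied seed into independent substreams, one per
#' named pipeline stage, so that e.g. adding phenome traits does not perturb
#' genotype draws. The derived seed is always in [1, 2^31 - 2].
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. "panel", "cohort", "phenome").
#' @return An integer seed for the stage.
#' @keywords internal
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (abs(as.numeric(seed)) %% m)
  # two rounds of a Lehmer-style mix keep substreams well separated
  s <- (s * 48271 + h) %% m
  s <- (s * 69621 + 1) %% m
  as.integer(s + 1L)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() wrapper carrying a class so tests can assert on error types
abort_input <- function(msg, class = "mrphewas_input_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort_input(sprintf("`%s` must be a finite numeric scalar", name))
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok)
    abort_input(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s",
                        name, x,
                        if (strict) "(" else "[", lower, upper,
                        if (strict) ")" else "]"))
  invisible(x)
}

# residualize columns of a matrix (or a vector) on a covariate matrix,
# including an intercept; used for partial regressions throughout
residualize <- function(x, covariates = NULL) {
  x <- as.matrix(x)
  z <- cbind(rep(1, nrow(x)), covariates)
  qz <- qr(z)
  x - qr.fitted(qz, x)
}

fmt_pct <- function(x) sprintf("%.1f%%", 100 * x)
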