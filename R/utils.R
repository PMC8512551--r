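# Shared internal helpers.

# Evaluate `code` under a locally seeded RNG when `seed` is given, otherwise
# consume the caller's RNG stream.  Every generator funnels its randomness
# through this so a seeded call is bit-reproducible and an unseeded call
# composes with an enclosing seeded context (e.g. generate_cohort()).
with_rng <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g (got %g)", name, upper, x), call. = FALSE)
  }
  invisible(x)
}

# Quantile map onto a normal left-truncated at `floor`: monotone in `p`, so
# rank correlations injected on the latent scale survive unchanged.
qnorm_truncated <- function(p, mean, sd, floor) {
  p_lo <- stats::pnorm(floor, mean, sd)
  stats::qnorm(p_lo + p * (1 - p_lo), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
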