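# Synthetic tensiomyography twitch responses.
#
# A twitch is modelled as a delayed difference of exponentials,
#   d(t) = A * c * (exp(-(t - t0)/tau_decay) - exp(-(t - t0)/tau_rise)),
# for t >= t0 and 0 before, with c chosen so the maximum equals A.  The
# shape has a single interior maximum whenever tau_decay > tau_rise, and
# its amplitude-fraction crossing times (the 10 % and 90 % levels that
# define the delay and contraction times) are cheap to locate to arbitrary
# precision, which makes the noiseless curve a convenient extraction
# oracle.

#' Ground truth for one synthetic twitch response
#'
#' @param amplitude_mm Target maximal displacement D_m (mm), > 0.
#' @param latency_ms Onset delay after the stimulus (ms), >= 0.
#' @param rise_tau_ms,decay_tau_ms Rise and decay time constants (ms);
#'   `decay_tau_ms > rise_tau_ms > 0` guarantees a unique interior maximum.
#' @param sample_rate_hz Sampling rate of the generated trace (Hz).
#' @param noise_sd_mm Additive Gaussian sensor noise SD (mm); 0 for a
#'   noiseless oracle trace.
#' @param seed Optional RNG seed.
#' @return An object of class `twitch_truth`.
#' @export
twitch_truth <- function(amplitude_mm, latency_ms = 10, rise_tau_ms = 20,
                         decay_tau_ms = 200, sample_rate_hz = 1000,
                         noise_sd_mm = 0, seed = NULL) {
  assert_scalar_number(amplitude_mm, "amplitude_mm", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(latency_ms, "latency_ms", lower = 0)
  assert_scalar_number(rise_tau_ms, "rise_tau_ms", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(decay_tau_ms, "decay_tau_ms", lower = rise_tau_ms,
                       strict_lower = TRUE)
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(noise_sd_mm, "noise_sd_mm", lower = 0)
  structure(list(amplitude_mm = amplitude_mm, latency_ms = latency_ms,
                 rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
                 sample_rate_hz = sample_rate_hz, noise_sd_mm = noise_sd_mm,
                 seed = seed),
            class = "twitch_truth")
}

# Normalized twitch shape: peak location and value of
# f(s) = exp(-s/decay) - exp(-s/rise), s = time since onset (ms).
twitch_shape <- function(rise_tau_ms, decay_tau_ms) {
  s_peak <- rise_tau_ms * decay_tau_ms / (decay_tau_ms - rise_tau_ms) *
    log(decay_tau_ms / rise_tau_ms)
  f <- function(s) exp(-s / decay_tau_ms) - exp(-s / rise_tau_ms)
  list(f = f, s_peak = s_peak, f_peak = f(s_peak))
}

# First time (ms since onset) at which the rising limb of the normalized
# shape crosses `frac` of its peak, solved to 1e-9 ms.
twitch_rise_crossing <- function(shape, frac) {
  target <- frac * shape$f_peak
  stats::uniroot(function(s) shape$f(s) - target,
                 lower = 0, upper = shape$s_peak,
                 f.lower = -target, tol = 1e-9)$root
}

#' Generate a synthetic TMG twitch trace
#'
#' Samples the parametric twitch at `truth$sample_rate_hz`, including a
#' 50 ms pre-stimulus baseline window, and attaches the analytically exact
#' parameters of the noiseless curve (computed by a dense-grid crossing
#' search at 100x the sampling rate) as oracle values.
#'
#' @param truth A [twitch_truth()].
#' @param muscle Optional muscle label (`"BF"`, `"GM"`, `"VL"`, `"VM"`).
#' @param oracle Compute and attach the dense-grid oracle values (set to
#'   `FALSE` to skip the dense grid when truth is tracked externally).
#' @return A `tmg_response`: `data.frame` with columns `time_ms`,
#'   `displacement_mm`, attribute `truth` holding the generating parameters
#'   and (when `oracle = TRUE`) the oracle `D_m_mm`, `T_d_ms`, `T_c_ms`.
#' @export
#' @examples
#' tw <- generate_twitch(twitch_truth(amplitude_mm = 5.84))
#' attr(tw, "truth")$oracle
generate_twitch <- function(truth, muscle = NA_character_, oracle = TRUE) {
  stopifnot(inherits(truth, "twitch_truth"))
  sh <- twitch_shape(truth$rise_tau_ms, truth$decay_tau_ms)
  scale <- truth$amplitude_mm / sh$f_peak
  dt_ms <- 1000 / truth$sample_rate_hz
  pre_ms <- 50
  total_ms <- truth$latency_ms + 6 * truth$decay_tau_ms
  tt <- seq(-pre_ms, total_ms, by = dt_ms)
  s <- tt - truth$latency_ms
  d <- ifelse(s > 0, scale * sh$f(pmax(s, 0)), 0)
  d <- with_rng(truth$seed, {
    if (truth$noise_sd_mm > 0) d + stats::rnorm(length(d), 0, truth$noise_sd_mm)
    else d
  })
  oracle_vals <- NULL
  if (oracle) {
    grid_dt <- dt_ms / 100
    gt <- seq(0, total_ms, by = grid_dt)
    gd <- ifelse(gt > truth$latency_ms,
                 scale * sh$f(pmax(gt - truth$latency_ms, 0)), 0)
    t10 <- dense_crossing(gt, gd, 0.10 * truth$amplitude_mm)
    t90 <- dense_crossing(gt, gd, 0.90 * truth$amplitude_mm)
    oracle_vals <- list(D_m_mm = truth$amplitude_mm, T_d_ms = t10,
                        T_c_ms = t90 - t10)
  }
  structure(data.frame(time_ms = tt, displacement_mm = d),
            truth = c(truth, list(oracle = oracle_vals)),
            muscle = muscle,
            class = c("tmg_response", "data.frame"))
}

# First upward crossing of `level` on a densely sampled rising curve,
# located by linear interpolation.
dense_crossing <- function(t, d, level) {
  i <- which(d >= level)[1]
  if (is.na(i) || i == 1L) {
    stop("level never crossed on the dense grid", call. = FALSE)
  }
  t[i - 1] + (level - d[i - 1]) / (d[i] - d[i - 1]) * (t[i] - t[i - 1])
}

# Invert the twitch shape: find (rise_tau_ms, latency_ms) such that the
# noiseless curve with the given decay tau has contraction time `tc_ms`
# (10 % -> 90 % rise) and delay time `td_ms` (stimulus -> 10 %).
solve_twitch_shape <- function(tc_ms, td_ms, decay_tau_ms = 200) {
  tc_of <- function(rise) {
    sh <- twitch_shape(rise, decay_tau_ms)
    twitch_rise_crossing(sh, 0.9) - twitch_rise_crossing(sh, 0.1)
  }
  lo <- 0.05
  hi <- 0.97 * decay_tau_ms
  if (tc_ms <= tc_of(lo) || tc_ms >= tc_of(hi)) {
    stop(sprintf("contraction time %.2f ms not attainable with decay tau %.0f ms",
                 tc_ms, decay_tau_ms), call. = FALSE)
  }
  rise <- stats::uniroot(function(r) tc_of(r) - tc_ms, lower = lo,
                         upper = hi, tol = 1e-7)$root
  t10 <- twitch_rise_crossing(twitch_shape(rise, decay_tau_ms), 0.1)
  if (td_ms <= t10) {
    stop(sprintf(paste0("delay time %.2f ms not attainable: the rising limb ",
                        "alone needs %.2f ms to reach 10%%"), td_ms, t10),
         call. = FALSE)
  }
  list(rise_tau_ms = rise, latency_ms = td_ms - t10, decay_tau_ms = decay_tau_ms)
}
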