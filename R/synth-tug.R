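# Synthetic TUG distance-signal generation.
#
# The trajectory is built so that the time spent inside each distance band
# equals the requested subtask duration exactly (in continuous time), which
# makes the generator usable as a segmentation oracle: sit-up and sit-down
# use quarter-cosine easings (the participant accelerates away from / decays
# into the seated rest position), the two walk phases are constant-velocity,
# and the turnaround is a raised-sine excursion above the turn boundary.

#' Ground-truth profile of one TUG performance
#'
#' Describes how long a simulated participant spends in each of the five
#' subtasks, plus the seated distance from the sensor and the apex distance
#' reached during the turnaround.  Defaults are the cohort mean subtask
#' durations of elderly nursing-home residents.
#'
#' @param sit_up_s,walk_forward_s,turn_s,walk_back_s,sit_down_s Subtask
#'   durations in seconds; all must be positive.
#' @param seated_distance_m Distance from the sensor while seated (m); must
#'   be below the 0.10 m seated-start threshold.
#' @param turn_apex_m Maximal distance reached during the turn (m); must lie
#'   inside the turn band, 3.20 to 3.50 m.
#' @return An object of class `tug_profile`.
#' @seealso [generate_tug_signal()], [random_tug_profiles()]
#' @export
#' @examples
#' tug_profile(sit_up_s = 3, walk_forward_s = 3, turn_s = 2,
#'             walk_back_s = 3, sit_down_s = 3)
tug_profile <- function(sit_up_s = 4.51, walk_forward_s = 3.78, turn_s = 3.00,
                        walk_back_s = 4.41, sit_down_s = 4.59,
                        seated_distance_m = 0.05, turn_apex_m = 3.35) {
  durations <- c(sit_up_s = sit_up_s, walk_forward_s = walk_forward_s,
                 turn_s = turn_s, walk_back_s = walk_back_s,
                 sit_down_s = sit_down_s)
  for (nm in names(durations)) {
    assert_scalar_number(durations[[nm]], nm, lower = 0, strict_lower = TRUE)
  }
  assert_scalar_number(seated_distance_m, "seated_distance_m", lower = 0)
  if (seated_distance_m >= 0.10) {
    stop("`seated_distance_m` must be < 0.10 m (the seated-start threshold)",
         call. = FALSE)
  }
  assert_scalar_number(turn_apex_m, "turn_apex_m", lower = 3.20, upper = 3.50)
  structure(
    list(sit_up_s = sit_up_s, walk_forward_s = walk_forward_s,
         turn_s = turn_s, walk_back_s = walk_back_s, sit_down_s = sit_down_s,
         seated_distance_m = seated_distance_m, turn_apex_m = turn_apex_m),
    class = "tug_profile"
  )
}

#' Ultrasonic sensor noise model
#'
#' @param quantization_m Reading resolution in metres; distances are rounded
#'   to the nearest multiple.  The default 0.03 m matches the 3 cm accuracy
#'   of the ultrasonic rangefinder.
#' @param gaussian_sd_m Standard deviation of additive Gaussian noise (m),
#'   applied before quantization.
#' @param dropout_prob Per-sample probability of a missing reading (`NA`),
#'   emulating lost echoes.
#' @param seed Optional RNG seed; when `NULL` the caller's RNG stream is
#'   consumed.
#' @return An object of class `tug_noise_model`.
#' @export
noise_model <- function(quantization_m = 0.03, gaussian_sd_m = 0.03,
                        dropout_prob = 0.01, seed = NULL) {
  assert_scalar_number(quantization_m, "quantization_m", lower = 0)
  assert_scalar_number(gaussian_sd_m, "gaussian_sd_m", lower = 0)
  assert_scalar_number(dropout_prob, "dropout_prob", lower = 0)
  if (dropout_prob >= 1) stop("`dropout_prob` must be < 1", call. = FALSE)
  structure(list(quantization_m = quantization_m,
                 gaussian_sd_m = gaussian_sd_m,
                 dropout_prob = dropout_prob, seed = seed),
            class = "tug_noise_model")
}

#' Noise-free sensor model
#'
#' Convenience wrapper for an ideal sensor: no additive noise, no
#' quantization, no dropout.  Useful for oracle fixtures.
#' @return A `tug_noise_model` with all noise sources disabled.
#' @export
noise_none <- function() {
  noise_model(quantization_m = 0, gaussian_sd_m = 0, dropout_prob = 0)
}

# Piecewise trajectory geometry for one profile.  b_low / b_high are the
# sit/walk and walk/turn band boundaries used by the segmenter (0.995 and
# 3.195 m by default); threshold is the seated-start criterion.
tug_geometry <- function(profile, b_low = 0.995, b_high = 3.195,
                         threshold = 0.10, lead_in_s = 2, lead_out_s = 2) {
  d0 <- profile$seated_distance_m
  frac_thr <- (threshold - d0) / (b_low - d0)
  # Fraction of the quarter-cosine rise / fall at which the seated-start
  # threshold is crossed; the easing is stretched so that the time between
  # that crossing and the band boundary equals the requested duration.
  u_rise <- (2 / pi) * acos(1 - frac_thr)
  u_fall <- (2 / pi) * asin(1 - frac_thr)
  T_rise <- profile$sit_up_s / (1 - u_rise)
  T_fall <- profile$sit_down_s / u_fall
  t_rs <- lead_in_s
  t1 <- t_rs + T_rise                      # crosses b_low going up
  t2 <- t1 + profile$walk_forward_s        # crosses b_high going up
  t3 <- t2 + profile$turn_s                # crosses b_high going down
  t4 <- t3 + profile$walk_back_s           # crosses b_low going down
  t_seat <- t4 + T_fall
  list(d0 = d0, b_low = b_low, b_high = b_high, apex = profile$turn_apex_m,
       t_rs = t_rs, t1 = t1, t2 = t2, t3 = t3, t4 = t4, t_seat = t_seat,
       T_rise = T_rise, T_fall = T_fall,
       t_start = t_rs + u_rise * T_rise,   # upward crossing of threshold
       t_end = t4 + profile$sit_down_s,    # downward crossing of threshold
       t_total = t_seat + lead_out_s)
}

tug_trajectory <- function(tt, g) {
  d <- numeric(length(tt))
  seg <- findInterval(tt, c(g$t_rs, g$t1, g$t2, g$t3, g$t4, g$t_seat))
  d[seg == 0L] <- g$d0
  i <- seg == 1L
  u <- (tt[i] - g$t_rs) / g$T_rise
  d[i] <- g$d0 + (g$b_low - g$d0) * (1 - cos(pi / 2 * u))
  i <- seg == 2L
  d[i] <- g$b_low + (g$b_high - g$b_low) * (tt[i] - g$t1) / (g$t2 - g$t1)
  i <- seg == 3L
  d[i] <- g$b_high + (g$apex - g$b_high) * sin(pi * (tt[i] - g$t2) / (g$t3 - g$t2))
  i <- seg == 4L
  d[i] <- g$b_high + (g$b_low - g$b_high) * (tt[i] - g$t3) / (g$t4 - g$t3)
  i <- seg == 5L
  u <- (tt[i] - g$t4) / g$T_fall
  d[i] <- g$d0 + (g$b_low - g$d0) * (1 - sin(pi / 2 * u))
  d[seg == 6L] <- g$d0
  d
}

#' Generate a synthetic TUG distance-over-time signal
#'
#' Simulates the distance-from-sensor signal of one TUG test at the device's
#' nominal sampling rate, together with the ground-truth subtask boundary
#' times.  The continuous trajectory spends exactly the profile's durations
#' inside the sit (below 0.995 m), walk (0.995 to 3.195 m) and turn (above
#' 3.195 m) regions, so segmentation error can be measured against exact
#' truth.
#'
#' @param profile A [tug_profile()].
#' @param noise A [noise_model()]; use [noise_none()] for an ideal sensor.
#' @param sample_rate_hz Sampling rate (Hz); the device samples at 10 Hz.
#' @return A `tug_signal`: a `data.frame` with columns `time_s` and
#'   `distance_m` and attributes `truth` (list with `boundaries_s`, the six
#'   ground-truth boundary times, and `durations_s`) and `profile`.
#' @export
#' @examples
#' sig <- generate_tug_signal(tug_profile(), noise_none())
#' attr(sig, "truth")$durations_s
generate_tug_signal <- function(profile, noise = noise_model(),
                                sample_rate_hz = 10) {
  stopifnot(inherits(profile, "tug_profile"),
            inherits(noise, "tug_noise_model"))
  assert_scalar_number(sample_rate_hz, "sample_rate_hz",
                       lower = 0, strict_lower = TRUE)
  dt <- 1 / sample_rate_hz
  g <- tug_geometry(profile)
  seg_durs <- c(g$T_rise, g$t2 - g$t1, g$t3 - g$t2, g$t4 - g$t3, g$T_fall)
  if (any(seg_durs < dt)) {
    stop(sprintf(paste0("profile inconsistent with sampling: a movement ",
                        "segment lasts %.3f s, shorter than one sample ",
                        "period (%.3f s)"), min(seg_durs), dt), call. = FALSE)
  }
  tt <- seq(0, g$t_total, by = dt)
  d <- tug_trajectory(tt, g)
  d <- with_rng(noise$seed, {
    if (noise$gaussian_sd_m > 0) {
      d <- d + stats::rnorm(length(d), 0, noise$gaussian_sd_m)
    }
    if (noise$quantization_m > 0) {
      d <- round(d / noise$quantization_m) * noise$quantization_m
    }
    d <- pmax(d, 0)
    if (noise$dropout_prob > 0) {
      d[stats::runif(length(d)) < noise$dropout_prob] <- NA_real_
    }
    d
  })
  truth <- list(
    boundaries_s = c(start = g$t_start, sit_to_walk = g$t1,
                     walk_to_turn = g$t2, turn_to_walk = g$t3,
                     walk_to_sit = g$t4, end = g$t_end),
    durations_s = c(sit_up_s = profile$sit_up_s,
                    walk_forward_s = profile$walk_forward_s,
                    turn_s = profile$turn_s,
                    walk_back_s = profile$walk_back_s,
                    sit_down_s = profile$sit_down_s,
                    total_s = g$t_end - g$t_start)
  )
  structure(data.frame(time_s = tt, distance_m = d),
            truth = truth, profile = profile,
            sample_rate_hz = sample_rate_hz,
            class = c("tug_signal", "data.frame"))
}

#' Draw random TUG profiles around the cohort population moments
#'
#' Subtask durations are drawn from normal distributions left-truncated at
#' 0.5 s (five sample periods at 10 Hz; shorter phases are not resolvable by
#' the sensor), the turn apex uniformly from 3.30 to 3.50 m.
#'
#' @param n Number of profiles.
#' @param moments A `data.frame` with columns `subtask`, `mean`, `sd` as
#'   returned by [tug_population_moments()].
#' @param seed Optional RNG seed.
#' @return A list of [tug_profile()] objects.
#' @export
random_tug_profiles <- function(n, moments = tug_population_moments(),
                                seed = NULL) {
  stopifnot(n >= 1)
  with_rng(seed, {
    lapply(seq_len(n), function(i) {
      dur <- vapply(c("sit_up", "walk_forward", "turn", "walk_back",
                      "sit_down"), function(s) {
        row <- moments[moments$subtask == s, ]
        qnorm_truncated(stats::runif(1), row$mean, row$sd,
                        floor = min_subtask_duration_s())
      }, numeric(1))
      tug_profile(sit_up_s = dur[["sit_up"]],
                  walk_forward_s = dur[["walk_forward"]],
                  turn_s = dur[["turn"]],
                  walk_back_s = dur[["walk_back"]],
                  sit_down_s = dur[["sit_down"]],
                  turn_apex_m = stats::runif(1, 3.30, 3.50))
    })
  })
}

# Shortest subtask duration the generator will produce (s).
min_subtask_duration_s <- function() 0.5
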