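make_signal <- function(time_s, distance_m) {
  tugtmg:::as_tug_signal(data.frame(time_s = time_s,
                                    distance_m = distance_m))
}

# Hand-built trapezoid test: seated, linear rise to the apex, dwell, linear
# descent, seated again.
trapezoid_signal <- function(apex = 3.35, dwell = 3, speed = 0.5,
                             seated = 0.05, dt = 0.1) {
  rise <- (apex - seated) / speed
  t <- seq(0, 2 + rise + dwell + rise + 2, by = dt)
  d <- ifelse(t < 2, seated,
         ifelse(t < 2 + rise, seated + speed * (t - 2),
           ifelse(t < 2 + rise + dwell, apex,
             ifelse(t < 2 + 2 * rise + dwell,
                    apex - speed * (t - 2 - rise - dwell), seated))))
  make_signal(t, d)
}

test_that("preprocess is transparent on clean monotone-in-window data", {
  sig <- generate_tug_signal(canonical_profile(), noise_none())
  ps <- tug_preprocess(sig)
  apex <- which.max(sig$distance_m)
  away <- abs(seq_along(sig$distance_m) - apex) > 2
  expect_equal(ps$distance_m[away], sig$distance_m[away])
  # the only non-monotone window is the turn apex, where the median can
  # shave at most the local curvature
  expect_lt(max(abs(ps$distance_m - sig$distance_m)), 0.01)
  expect_identical(ps$time_s, sig$time_s)
})

test_that("preprocess interpolates isolated dropouts linearly", {
  sig <- make_signal(seq(0, 1, 0.1), c(1.0, 1.0, 1.0, 1.0, 1.00, NA,
                                       1.20, 1.2, 1.2, 1.2, 1.2))
  ps <- tug_preprocess(sig, band_config(smoothing_window = 1))
  expect_equal(ps$distance_m[6], 1.10)
  expect_equal(attr(ps, "n_interpolated"), 1L)
})

test_that("preprocess rejects signals with more than 20% invalid samples", {
  d <- rep(1, 100)
  d[1:25] <- NA
  expect_error(tug_preprocess(make_signal(seq(0, 9.9, 0.1), d)),
               "unusable")
  d[1:25] <- 7  # out of sensor range counts as invalid too
  expect_error(tug_preprocess(make_signal(seq(0, 9.9, 0.1), d)),
               "unusable")
})

test_that("start detection finds the end of the seated run", {
  t <- seq(0, 10, 0.1)
  d <- ifelse(t <= 2, 0.05, pmin(0.05 + 0.4 * (t - 2), 3.0))
  expect_equal(tug_detect_start(make_signal(t, d)), 2.0, tolerance = 0.11)
  expect_error(tug_detect_start(make_signal(t, d + 1)), "no seated start")
})

test_that("start recovery matches generator ground truth within one sample", {
  sig <- generate_tug_signal(canonical_profile(), noise_none())
  start <- tug_detect_start(sig)
  expect_equal(start, attr(sig, "truth")$boundaries_s[["start"]],
               tolerance = 0.1)
})

test_that("noiseless canonical fixture is segmented to the profiled durations", {
  sig <- generate_tug_signal(canonical_profile(), noise_none())
  st <- tug_segment(sig)
  expect_equal(unname(subtask_vec(st)),
               c(4.51, 3.78, 3.00, 4.41, 4.59), tolerance = 0.1 / 4)
  expect_equal(st$total_s, 20.29, tolerance = 0.2 / 20)
  expect_false(st$truncated)
})

test_that("turnaround credits the dwell time above the turn boundary", {
  sig <- trapezoid_signal(apex = 3.35, dwell = 3, speed = 0.5)
  st <- tug_segment(sig)
  # dwell at apex plus the two linear traversals of [3.195, 3.35]
  expected <- 3 + 2 * (3.35 - 3.195) / 0.5
  expect_equal(st$turn_s, expected, tolerance = 1e-6)
})

test_that("the five durations sum to the total (partition invariant)", {
  sig <- generate_tug_signal(canonical_profile(), noise_none())
  st <- tug_segment(sig)
  expect_equal(sum(subtask_vec(st)), st$total_s, tolerance = 1e-9)
  withr::local_seed(91)
  for (p in random_tug_profiles(5)) {
    st <- tug_segment(generate_tug_signal(p, noise_model()))
    expect_equal(sum(subtask_vec(st)), st$total_s, tolerance = 1e-9)
  }
})

test_that("time reversal swaps sit-up with sit-down and the walks", {
  sig <- generate_tug_signal(tug_profile(3, 4, 2, 4, 3), noise_none())
  st <- tug_segment(sig)
  rsig <- make_signal(max(sig$time_s) - rev(sig$time_s),
                      rev(sig$distance_m))
  rst <- tug_segment(rsig)
  expect_equal(st$sit_up_s, rst$sit_down_s)
  expect_equal(st$walk_forward_s, rst$walk_back_s)
  expect_equal(st$turn_s, rst$turn_s)
  expect_equal(st$total_s, rst$total_s)
})

test_that("speeding the signal up by k divides every duration by k", {
  sig <- generate_tug_signal(canonical_profile(), noise_none())
  st <- tug_segment(sig)
  k <- 2
  fast <- make_signal(sig$time_s / k, sig$distance_m)
  stf <- tug_segment(fast)
  expect_equal(subtask_vec(stf), subtask_vec(st) / k, tolerance = 1e-9)
  expect_equal(stf$total_s, st$total_s / k, tolerance = 1e-9)
})

test_that("interpolated crossings match a dense-grid search on noiseless data", {
  sig <- generate_tug_signal(canonical_profile(), noise_none())
  st <- tug_segment(sig)
  b <- st$boundary_times_s
  expect_equal(b[["sit_to_walk"]],
               brute_crossing(sig$time_s, sig$distance_m, 0.995, "up")[1],
               tolerance = 1e-6)
  expect_equal(b[["walk_to_turn"]],
               brute_crossing(sig$time_s, sig$distance_m, 3.195, "up")[1],
               tolerance = 1e-6)
  expect_equal(b[["turn_to_walk"]],
               brute_crossing(sig$time_s, sig$distance_m, 3.195, "down")[1],
               tolerance = 1e-6)
  expect_equal(b[["walk_to_sit"]],
               brute_crossing(sig$time_s, sig$distance_m, 0.995, "down")[1],
               tolerance = 1e-6)
})

test_that("incomplete and ambiguous trajectories are rejected with diagnostics", {
  # Never reaches the turn band.
  t <- seq(0, 24, 0.1)
  d <- ifelse(t <= 2, 0.05,
         ifelse(t <= 10, pmin(0.05 + 0.4 * (t - 2), 2.5),
           ifelse(t <= 14, 2.5, pmax(2.5 - 0.4 * (t - 14), 0.05))))
  expect_error(tug_segment(make_signal(t, d)), "incomplete test")
  # Two separated excursions above the turn boundary.
  bump <- function(tc, w, a) a * exp(-((t - tc) / w)^2)
  d2 <- pmax(0.05, bump(8, 1.5, 3.4) + bump(16, 1.5, 3.4))
  d2[t <= 2] <- 0.05
  expect_error(tug_segment(make_signal(t, d2)), "ambiguous")
})

test_that("end detection flags truncated traces instead of failing", {
  sig <- generate_tug_signal(canonical_profile(), noise_none())
  keep <- sig$time_s <= attr(sig, "truth")$boundaries_s[["walk_to_sit"]] + 0.3
  cut <- make_signal(sig$time_s[keep], sig$distance_m[keep])
  st <- tug_segment(cut)
  expect_true(st$truncated)
  expect_equal(st$boundary_times_s[["end"]], max(cut$time_s))
})

test_that("end detection returns the first sample of the seated tail", {
  sig <- trapezoid_signal()
  res <- tug_detect_end(sig, after = 0)
  first_seated <- min(sig$time_s[sig$distance_m < 0.10 &
                                   sig$time_s > max(sig$time_s) - 2.05])
  expect_false(res$truncated)
  expect_equal(res$time, first_seated, tolerance = 0.1)
})
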