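# TUG distance-signal segmentation into the five subtask times.
#
# The device reports distance from a chair-mounted ultrasonic sensor, so
# subtasks map onto distance bands: sit-up / sit-down below 0.99 m,
# walk-forward / walk-back between 1 and 3.19 m, turnaround between 3.20 and
# 3.50 m.  Band boundaries are crossed once per phase in a clean test;
# crossing times are located by linear interpolation between the straddling
# samples and a hysteresis margin suppresses chatter from the 3 cm sensor
# noise.

#' Distance-band configuration for TUG segmentation
#'
#' @param sit_band,walk_band,turn_band Two-element numeric vectors giving
#'   the lower and upper edge (m) of the sit, walk and turn bands.  The gap
#'   between adjacent band edges (0.99/1.00 and 3.19/3.20 m) is treated as a
#'   single crossing boundary at the midpoint (0.995 and 3.195 m).
#' @param start_threshold_m Seated criterion (m): a test starts/ends with
#'   the participant closer than this.
#' @param hysteresis_m Margin (m) a trace must travel beyond a boundary
#'   before a re-cross is accepted as a new crossing; must exceed the sensor
#'   resolution to be effective.
#' @param smoothing_window Odd window length (samples) of the running-median
#'   filter applied by [tug_preprocess()]; `1` disables smoothing.
#' @param edge_smoothing_window Odd window length (samples) of the wider
#'   running median used only while locating the seated start/end.  Near the
#'   chair the distance changes slowly, so a running median -- which is
#'   exactly transparent on monotone stretches -- can be widened there to
#'   suppress sensor noise without biasing the crossing.
#' @param min_seated_s Minimum dwell (s) below `start_threshold_m` that
#'   counts as sitting at the start/end of a test.
#' @return An object of class `band_config`.
#' @export
band_config <- function(sit_band = c(0, 0.99), walk_band = c(1.00, 3.19),
                        turn_band = c(3.20, 3.50), start_threshold_m = 0.10,
                        hysteresis_m = 0.05, smoothing_window = 5,
                        edge_smoothing_window = 9, min_seated_s = 1.0) {
  stopifnot(length(sit_band) == 2, length(walk_band) == 2,
            length(turn_band) == 2)
  if (!(sit_band[1] < sit_band[2] && sit_band[2] < walk_band[1] &&
        walk_band[1] < walk_band[2] && walk_band[2] < turn_band[1] &&
        turn_band[1] < turn_band[2])) {
    stop("bands must be ordered, non-overlapping and contiguous: sit < walk < turn",
         call. = FALSE)
  }
  assert_scalar_number(start_threshold_m, "start_threshold_m",
                       lower = 0, strict_lower = TRUE)
  if (start_threshold_m >= sit_band[2]) {
    stop("`start_threshold_m` must be below the sit band's upper edge",
         call. = FALSE)
  }
  assert_scalar_number(hysteresis_m, "hysteresis_m", lower = 0)
  for (w in c(smoothing_window = smoothing_window,
              edge_smoothing_window = edge_smoothing_window)) {
    if (w < 1 || w %% 2 == 0) {
      stop("smoothing windows must be odd positive sample counts",
           call. = FALSE)
    }
  }
  assert_scalar_number(min_seated_s, "min_seated_s", lower = 0)
  structure(list(sit_band = sit_band, walk_band = walk_band,
                 turn_band = turn_band, start_threshold_m = start_threshold_m,
                 hysteresis_m = hysteresis_m,
                 smoothing_window = as.integer(smoothing_window),
                 edge_smoothing_window = as.integer(edge_smoothing_window),
                 min_seated_s = min_seated_s,
                 low_boundary_m = mean(c(sit_band[2], walk_band[1])),
                 high_boundary_m = mean(c(walk_band[2], turn_band[1])),
                 range_m = c(0, 6.0)),
            class = "band_config")
}

as_tug_signal <- function(df, meta = NULL) {
  stopifnot(is.data.frame(df), all(c("time_s", "distance_m") %in% names(df)))
  if (nrow(df) < 2) stop("a distance signal needs at least 2 samples",
                         call. = FALSE)
  if (any(diff(df$time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(df[c("time_s", "distance_m")], meta = meta,
            class = c("tug_signal", "data.frame"))
}

#' Clean a raw TUG distance signal
#'
#' Replaces dropout samples (non-finite readings or values outside the
#' sensor's 0 to 6 m range) by linear interpolation between valid
#' neighbours, then applies an odd-window running median.  Timestamps are
#' unchanged.
#'
#' @param signal A `tug_signal` (see [generate_tug_signal()] or
#'   [read_distance_csv()]).
#' @param config A [band_config()].
#' @return The cleaned `tug_signal`; attribute `n_interpolated` counts
#'   replaced samples.
#' @export
tug_preprocess <- function(signal, config = band_config()) {
  t <- signal$time_s
  d <- signal$distance_m
  bad <- !is.finite(d) | d < config$range_m[1] | d > config$range_m[2]
  if (mean(bad) > 0.20) {
    stop(sprintf("signal unusable: %.0f%% of %d samples are invalid (> 20%% limit)",
                 100 * mean(bad), length(d)), call. = FALSE)
  }
  if (any(bad)) {
    d[bad] <- NA_real_
    d <- stats::approx(t[!is.na(d)], d[!is.na(d)], xout = t, rule = 2)$y
  }
  d_unsmoothed <- d
  k <- config$smoothing_window
  if (k >= 3 && length(d) > k) {
    d <- stats::runmed(d, k, endrule = "keep")
  }
  out <- signal
  raw <- attr(signal, "raw_interp")
  out$distance_m <- as.numeric(d)
  attr(out, "n_interpolated") <- sum(bad)
  # Dropout-interpolated but unsmoothed samples: model-based boundary
  # refinements fit on these, since the median filter correlates the noise.
  attr(out, "raw_interp") <- raw %||% as.numeric(d_unsmoothed)
  out
}

# Schmitt-trigger crossing detector.  State is "low" when d < level -
# low_margin and "high" when d > level + high_margin; samples in between
# inherit the previous state, so excursions smaller than the margin never
# produce a crossing.  Each accepted transition is timestamped by linear
# interpolation of the last straddling sample pair at `level`.
schmitt_crossings <- function(time_s, d, level, low_margin, high_margin) {
  s <- integer(length(d))
  s[d > level + high_margin] <- 1L
  s[d < level - low_margin] <- -1L
  nz <- which(s != 0L)
  empty <- data.frame(direction = character(0), time = numeric(0),
                      index = integer(0), run_first = integer(0))
  if (length(nz) == 0L) return(list(events = empty, state = s))
  pos <- findInterval(seq_along(s), nz)
  eff <- s[nz][pmax(pos, 1L)]            # leading mid-zone inherits first state
  r <- rle(eff)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  if (length(r$values) < 2L) return(list(events = empty, state = eff))
  n_ev <- length(r$values) - 1L
  ev_dir <- character(n_ev)
  ev_time <- numeric(n_ev)
  ev_index <- integer(n_ev)
  for (q in seq_len(n_ev)) {
    up <- r$values[q] == -1L && r$values[q + 1L] == 1L
    j <- starts[q + 1L]                  # first committed sample of new state
    # All candidate crossings in the transition gap (between the last
    # committed sample of the previous state and the commit); taking their
    # median is unbiased under noise chatter, whereas the first (last)
    # candidate is systematically early (late) when the slope through the
    # boundary is shallow.
    prev_committed <- which(s[starts[q]:(j - 1L)] == r$values[q])
    i0 <- starts[q] + prev_committed[length(prev_committed)] - 1L
    rng <- i0:min(j, length(d) - 1L)
    ks <- if (up) {
      rng[d[rng] <= level & d[rng + 1L] > level]
    } else {
      rng[d[rng] >= level & d[rng + 1L] < level]
    }
    tcs <- time_s[ks] + (level - d[ks]) / (d[ks + 1L] - d[ks]) *
      (time_s[ks + 1L] - time_s[ks])
    ev_dir[q] <- if (up) "up" else "down"
    ev_time[q] <- stats::median(tcs)
    ev_index[q] <- ks[ceiling(length(ks) / 2)]
  }
  list(events = data.frame(direction = ev_dir, time = ev_time,
                           index = ev_index,
                           run_first = starts[seq_len(n_ev)]),
       state = eff)
}

# High-frequency noise level of a uniformly sampled signal, estimated from
# second differences (insensitive to smooth trends).
signal_noise_sd <- function(d) stats::mad(diff(diff(d))) / sqrt(6)

# Noise level above which the model-based boundary refinements switch on.
# Below it, plain interpolated crossings are already exact.
refine_noise_gate_m <- function() 0.005

# Rest-to-motion corner model.  Near the chair the participant is at rest
# and leaves it with zero velocity, so the distance follows
#   d(t) = d0               for t <= ts,
#   d(t) = d0 + c (t - ts)^2 for t >  ts
# to second order.  Fitting this over the seated run and the early rise
# pools tens of samples into the start estimate, which a single threshold
# crossing cannot do when the approach slope is shallow compared to the
# sensor noise.  Returns the model's upward crossing of `thr`, or NA when
# the fit is degenerate.  For the end of the test the caller passes the
# time-reversed signal.
fit_corner_crossing <- function(t, d, first, k, thr, rise_limit_m = 0.45) {
  n <- length(t)
  dt <- stats::median(diff(t))
  hi <- k
  while (hi < n && d[hi] < rise_limit_m) hi <- hi + 1L
  lo <- max(first, k - as.integer(round(3 / dt)))
  idx <- lo:hi
  if (length(idx) < 8L) return(NA_real_)
  tt <- t[idx]
  dd <- d[idx]
  cand <- seq(tt[1], t[k], by = dt / 2)
  best_sse <- Inf
  best <- NULL
  for (ts in cand) {
    x <- pmax(tt - ts, 0)^2
    mx <- mean(x)
    sxx <- sum((x - mx)^2)
    if (sxx < 1e-12) next
    c1 <- sum((x - mx) * (dd - mean(dd))) / sxx
    c0 <- mean(dd) - c1 * mx
    sse <- sum((dd - c0 - c1 * x)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- c(ts, c0, c1)
    }
  }
  if (is.null(best) || best[3] <= 0 || thr <= best[2]) return(NA_real_)
  out <- best[1] + sqrt((thr - best[2]) / best[3])
  if (abs(out - t[k]) > 1) NA_real_ else out
}

# Smooth-ease template for the sit-to-stand / stand-to-sit distance ramp:
#   d(t) = d0 + a * (1 - cos(pi/2 * clamp((t - ts)/T, 0, 1))),
# a raised-cosine rest-to-motion ramp with onset ts, rate 1/T and free
# offset/scale.  Given (ts, T) the model is linear in (d0, a), so those are
# profiled out and only (ts, T) are optimized.  Returns the model's
# crossing of `thr`, or NA when degenerate.  The template pools the whole
# early rise into the boundary estimate, which matters when the approach
# slope near the seated threshold is shallow compared to the sensor noise.
fit_ease_crossing <- function(t, d, first, k, thr, rise_limit_m = 0.90) {
  n <- length(t)
  dt <- stats::median(diff(t))
  hi <- k
  while (hi < n && d[hi] < rise_limit_m) hi <- hi + 1L
  lo <- max(first, k - as.integer(round(3 / dt)))
  idx <- lo:hi
  if (length(idx) < 10L) return(NA_real_)
  tt <- t[idx]
  dd <- d[idx]
  profile_fit <- function(par) {
    ts <- par[1]
    Tr <- par[2]
    if (Tr < 0.5 || Tr > 40 || ts < tt[1] - 5 || ts > tt[length(tt)]) {
      return(list(sse = Inf))
    }
    u <- pmin(pmax((tt - ts) / Tr, 0), 1)
    x <- 1 - cos(pi / 2 * u)
    mx <- mean(x)
    vx <- sum((x - mx)^2)
    if (vx < 1e-10) return(list(sse = Inf))
    a <- sum((x - mx) * (dd - mean(dd))) / vx
    d0 <- mean(dd) - a * mx
    list(sse = sum((dd - d0 - a * x)^2), a = a, d0 = d0)
  }
  # Initial guess from the coarse crossing and the time the rise needs to
  # reach the upper fit limit.
  T0 <- max(1, (t[hi] - t[k]) / 0.7)
  init <- c(t[k] - 0.21 * T0, T0)
  opt <- stats::optim(init, function(p) profile_fit(p)$sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 120, reltol = 1e-7))
  pf <- profile_fit(opt$par)
  if (!is.finite(pf$sse) || pf$a <= 0) return(NA_real_)
  frac <- (thr - pf$d0) / pf$a
  if (!is.finite(frac) || frac <= 0 || frac >= 1) return(NA_real_)
  opt$par[1] + opt$par[2] * (2 / pi) * acos(1 - frac)
}

# Turn-excursion template: linear walking limbs joined by a sinusoidal
# excursion of length Tn starting at t2,
#   d(t) = b + s1 (t - t2)            for t <= t2,
#          b + A sin(pi (t - t2)/Tn)  for t2 < t < t2 + Tn,
#          b + s2 (t - t2 - Tn)       for t >= t2 + Tn.
# Given (t2, Tn) the model is linear in (b, s1, s2, A), so those are
# profiled out.  Fitting the whole walk-turn-walk section pools every
# sample of the excursion into the two boundary crossings, which a local
# estimator cannot do when the excursion is slow and shallow.  Returns
# c(up, down) crossing times of `level`, or NULL when degenerate.
fit_turn_template <- function(t, d, level, t_up, t_down, lo_s, hi_s) {
  sel <- which(t >= lo_s & t <= hi_s)
  if (length(sel) < 10L) return(NULL)
  tt <- t[sel]
  dd <- d[sel]
  profile_fit <- function(par) {
    t2 <- par[1]
    Tn <- par[2]
    if (Tn < 0.3 || Tn > 30 || t2 < tt[1] - 2 || t2 + Tn > tt[length(tt)] + 2) {
      return(list(sse = Inf))
    }
    u <- (tt - t2) / Tn
    X <- cbind(1, pmin(tt - t2, 0), pmax(tt - t2 - Tn, 0),
               ifelse(u > 0 & u < 1, sin(pi * u), 0))
    fit <- stats::.lm.fit(X, dd)
    list(sse = sum(fit$residuals^2), coef = fit$coefficients)
  }
  opt <- stats::optim(c(t_up, max(0.5, t_down - t_up)),
                      function(p) profile_fit(p)$sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 150, reltol = 1e-7))
  pf <- profile_fit(opt$par)
  if (!is.finite(pf$sse)) return(NULL)
  t2 <- opt$par[1]
  Tn <- opt$par[2]
  b <- pf$coef[1]
  s1 <- pf$coef[2]
  s2 <- pf$coef[3]
  A <- pf$coef[4]
  if (A <= 0) return(NULL)
  cross <- function(at_end) {
    anchor <- if (at_end) t2 + Tn else t2
    slope <- if (at_end) s2 else s1
    if (b >= level) {
      if ((at_end && slope >= 0) || (!at_end && slope <= 0)) return(NA_real_)
      anchor + (level - b) / slope
    } else {
      val <- (level - b) / A
      if (val >= 1) return(NA_real_)
      if (at_end) anchor - Tn / pi * asin(val) else anchor + Tn / pi * asin(val)
    }
  }
  up <- cross(FALSE)
  down <- cross(TRUE)
  if (is.na(up) || is.na(down) || up >= down ||
      abs(up - t_up) > 1.5 || abs(down - t_down) > 1.5) {
    return(NULL)
  }
  c(up, down)
}

# Local change-point ("kink") model for a band-boundary crossing.  The
# walking limb and the turn limb meet at the boundary with different
# speeds, so interpolated crossings scatter asymmetrically under noise
# (chatter reaches further onto the shallow limb) and simple median
# re-location stays biased.  Fitting a continuous two-slope model with a
# quadratic term on the trailing limb
#   d(t) = a + b1 (t - tb)  for t <= tb,   a + b2 (t - tb) + b3 (t - tb)^2
# over the unsmoothed samples around the coarse crossing and intersecting
# it with the boundary level removes that bias.  Returns NA when the fit
# is degenerate.
fit_kink_crossing <- function(t, d, level, t_coarse, lo_s = -Inf,
                              hi_s = Inf, halfwidth_s = 0.8) {
  sel <- which(t >= max(t_coarse - halfwidth_s, lo_s) &
                 t <= min(t_coarse + halfwidth_s, hi_s))
  if (length(sel) < 8L) return(NA_real_)
  tt <- t[sel]
  dd <- d[sel]
  dt <- stats::median(diff(t))
  best_sse <- Inf
  best <- NULL
  for (tb in seq(tt[1] + 2 * dt, tt[length(tt)] - 2 * dt, by = dt / 2)) {
    X <- cbind(1, pmin(tt - tb, 0), pmax(tt - tb, 0), pmax(tt - tb, 0)^2)
    fit <- stats::.lm.fit(X, dd)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- c(tb, fit$coefficients)
    }
  }
  if (is.null(best)) return(NA_real_)
  tb <- best[1]
  a <- best[2]
  b1 <- best[3]
  b2 <- best[4]
  c1 <- if (b1 != 0) tb + (level - a) / b1 else NA_real_
  c2 <- if (b2 != 0) tb + (level - a) / b2 else NA_real_
  cand <- c(if (!is.na(c1) && c1 <= tb) c1,
            if (!is.na(c2) && c2 > tb) c2)
  if (!length(cand)) return(NA_real_)
  out <- cand[which.min(abs(cand - t_coarse))]
  if (abs(out - t_coarse) > halfwidth_s) NA_real_ else out
}

# Re-locate a coarse crossing time on a more heavily smoothed copy of the
# signal.  A running median is exactly transparent on monotone stretches
# (including slope kinks), so widening it near a boundary reduces the noise
# of the interpolated crossing without biasing it; the coarse Schmitt event
# detection stays on the lightly smoothed signal so that short turn-band
# excursions are not eroded away.  The median of the straddle candidates
# within `radius_s` of the coarse time is returned; if the smoothed copy
# has no straddle there (e.g. an eroded short excursion), the coarse time
# is kept.
relocate_crossing <- function(t, d_wide, level, t_coarse, direction,
                              radius_s = 2, lo_s = -Inf, hi_s = Inf) {
  n <- length(t)
  sel <- which(t >= max(t_coarse - radius_s, lo_s) &
                 t <= min(t_coarse + radius_s, hi_s))
  sel <- sel[sel < n]
  ks <- if (direction == "up") {
    sel[d_wide[sel] <= level & d_wide[sel + 1L] > level]
  } else {
    sel[d_wide[sel] >= level & d_wide[sel + 1L] < level]
  }
  if (length(ks) == 0L) return(t_coarse)
  tcs <- t[ks] + (level - d_wide[ks]) / (d_wide[ks + 1L] - d_wide[ks]) *
    (t[ks + 1L] - t[ks])
  stats::median(tcs)
}

# Seated-state runs relative to the start threshold.  Low state is defined
# without a lower margin (the seated distance itself may sit just under the
# threshold); brief pokes above the threshold that stay within the
# hysteresis margin do not end a seated run.  The wider edge median is
# applied first: the signal is monotone around the seated boundary, where a
# running median is exactly transparent, so this only removes noise.
seated_smooth <- function(d, config) {
  k <- config$edge_smoothing_window
  if (k >= 3 && length(d) > k) stats::runmed(d, k, endrule = "keep") else d
}

seated_runs <- function(time_s, d, config) {
  schmitt_crossings(time_s, d, config$start_threshold_m,
                    low_margin = 0, high_margin = config$hysteresis_m)
}

#' Detect the start of a TUG test
#'
#' The test starts when the participant leaves the chair: the start time is
#' the last sample below the seated threshold in the earliest run of at
#' least `min_seated_s` seconds below it that is followed by a sustained
#' rise.
#'
#' @inheritParams tug_preprocess
#' @param preprocessed Set to `TRUE` when `signal` has already been through
#'   [tug_preprocess()].
#' @param refine On noisy signals, refine the boundary with a rest-to-motion
#'   corner-model fit over the seated run and the early rise (see the
#'   package vignette); noiseless signals always use the plain sample rule.
#' @return Start time in seconds (scalar).
#' @export
tug_detect_start <- function(signal, config = band_config(),
                             preprocessed = FALSE, refine = TRUE) {
  if (!preprocessed) signal <- tug_preprocess(signal, config)
  t <- signal$time_s
  d <- seated_smooth(signal$distance_m, config)
  if (!any(d < config$start_threshold_m)) {
    stop("no seated start detected: signal never below the seated threshold",
         call. = FALSE)
  }
  dt <- stats::median(diff(t))
  sc <- seated_runs(t, d, config)
  ev <- sc$events
  ups <- ev[ev$direction == "up", , drop = FALSE]
  for (q in seq_len(nrow(ups))) {
    k <- ups$index[q]
    first <- ups$run_first[q]
    if (t[k] - t[first] + dt >= config$min_seated_s - 1e-9) {
      if (refine &&
          signal_noise_sd(signal$distance_m) > refine_noise_gate_m()) {
        # Corner fits on the unsmoothed and the smoothed samples, combined
        # with the coarse sample rule through a median: robust against a
        # wrong-branch fit while keeping the fit's precision.
        raw <- attr(signal, "raw_interp") %||% signal$distance_m
        # The coarse sample rule is itself noisy when the rise is shallow,
        # so the sanity gates around it are loose: a valid model fit is
        # preferred unless it strays far outside the seated-run context.
        r0 <- fit_ease_crossing(t, raw, first, k, config$start_threshold_m)
        if (!is.na(r0) && abs(r0 - t[k]) <= 1.5) return(r0)
        r1 <- fit_corner_crossing(t, raw, first, k, config$start_threshold_m)
        if (!is.na(r1) && abs(r1 - t[k]) <= 1) return(r1)
        return(t[k])
      }
      return(t[k])
    }
  }
  stop("no seated start detected: no sustained seated run followed by a rise",
       call. = FALSE)
}

#' Detect the end of a TUG test
#'
#' Symmetric with the start rule: the test ends at the first sample after
#' `after` at which the distance stays below the seated threshold for at
#' least `min_seated_s` seconds.  If the trace ends before the participant
#' is confirmed seated, the last sample time is returned and the test is
#' flagged as truncated.
#'
#' @inheritParams tug_detect_start
#' @param after Only consider seated runs starting after this time (s);
#'   normally the walk-back's downward crossing of the walk band edge.
#' @return A list with `time` (s) and logical `truncated`.
#' @export
tug_detect_end <- function(signal, config = band_config(), after = -Inf,
                           preprocessed = FALSE, refine = TRUE) {
  if (!preprocessed) signal <- tug_preprocess(signal, config)
  t <- signal$time_s
  d <- seated_smooth(signal$distance_m, config)
  dt <- stats::median(diff(t))
  sc <- seated_runs(t, d, config)
  ev <- sc$events
  n <- length(t)
  # Candidate seated runs: indices of first/last below-threshold sample.
  downs <- ev[ev$direction == "down", , drop = FALSE]
  run_starts <- integer(0)
  if (d[1] < config$start_threshold_m) run_starts <- 1L
  for (q in seq_len(nrow(downs))) {
    j <- downs$index[q] + 1L             # first sample back under the level
    while (j <= n && d[j] >= config$start_threshold_m) j <- j + 1L
    if (j <= n) run_starts <- c(run_starts, j)
  }
  ups <- ev[ev$direction == "up", , drop = FALSE]
  refine_time <- function(first, last) {
    # Mirror of the start refinement on the time-reversed trace.
    if (!refine ||
        signal_noise_sd(signal$distance_m) <= refine_noise_gate_m()) {
      return(t[first])
    }
    raw <- rev(attr(signal, "raw_interp") %||% signal$distance_m)
    tr <- t[n] - rev(t)
    kr <- n - first + 1L
    fr <- n - last + 1L
    r0 <- fit_ease_crossing(tr, raw, fr, kr, config$start_threshold_m)
    if (!is.na(r0) && abs(r0 - tr[kr]) <= 1.5) return(t[n] - r0)
    r1 <- fit_corner_crossing(tr, raw, fr, kr, config$start_threshold_m)
    if (!is.na(r1) && abs(r1 - tr[kr]) <= 1) return(t[n] - r1)
    t[first]
  }
  for (first in run_starts) {
    if (t[first] <= after) next
    nxt <- ups$index[ups$index >= first]
    last <- if (length(nxt)) nxt[1] else n
    span <- t[last] - t[first] + dt
    if (length(nxt) == 0L) {
      # Seated through to the end of the record.
      return(list(time = refine_time(first, last),
                  truncated = span < config$min_seated_s))
    }
    if (span >= config$min_seated_s - 1e-9) {
      return(list(time = refine_time(first, last), truncated = FALSE))
    }
  }
  list(time = t[n], truncated = TRUE)
}

#' Segment a TUG distance signal into subtask times
#'
#' Splits one test into sit-up, walk-forward, turnaround, walk-back and
#' sit-down durations plus the total time, using interpolated crossings of
#' the band boundaries: sit-up runs from the detected start to the upward
#' crossing of the sit/walk boundary, walk-forward to the upward crossing of
#' the walk/turn boundary, turnaround is the dwell at or beyond that
#' boundary, walk-back runs to the downward crossing of the sit/walk
#' boundary and sit-down to the detected end.
#'
#' @inheritParams tug_preprocess
#' @return An object of class `subtask_times`: a list with the five subtask
#'   durations, `total_s`, `boundary_times_s` (start, four interior
#'   crossings, end) and a `truncated` flag.
#' @export
#' @examples
#' sig <- generate_tug_signal(tug_profile(), noise_none())
#' tug_segment(sig)
tug_segment <- function(signal, config = band_config()) {
  ps <- tug_preprocess(signal, config)
  t <- ps$time_s
  d <- ps$distance_m
  h <- config$hysteresis_m
  start <- tug_detect_start(ps, config, preprocessed = TRUE)
  noisy <- signal_noise_sd(d) > refine_noise_gate_m()
  d_wide <- if (noisy) seated_smooth(d, config) else d

  low <- schmitt_crossings(t, d, config$low_boundary_m, h, h)$events
  t_up1 <- low$time[low$direction == "up" & low$time > start]
  if (length(t_up1) == 0L) {
    stop("incomplete test: trajectory never leaves the sit band",
         call. = FALSE)
  }
  t_up1 <- t_up1[1]

  high <- schmitt_crossings(t, d, config$high_boundary_m, h, h)$events
  hi_up <- high$time[high$direction == "up" & high$time > t_up1]
  if (length(hi_up) == 0L) {
    stop("incomplete test: no excursion into the turn band", call. = FALSE)
  }
  if (length(hi_up) > 1L) {
    stop(sprintf("ambiguous trajectory: %d separated turn-band excursions",
                 length(hi_up)), call. = FALSE)
  }
  t_up2 <- hi_up[1]
  hi_down <- high$time[high$direction == "down" & high$time > t_up2]
  if (length(hi_down) == 0L) {
    stop("incomplete test: trace ends inside the turn band", call. = FALSE)
  }
  t_down2 <- hi_down[length(hi_down)]

  t_down1 <- low$time[low$direction == "down" & low$time > t_down2]
  if (length(t_down1) == 0L) {
    stop("incomplete test: walk-back never re-enters the sit band",
         call. = FALSE)
  }
  t_down1 <- t_down1[1]

  if (noisy) {
    # Refine the four interior crossings: the sit/walk boundary crossings
    # are re-located on the wider median (kink-transparent, lower noise);
    # the walk/turn crossings, where the slope change is largest, use the
    # local change-point fit on the unsmoothed samples.  Windows are
    # clipped to the midpoints towards the neighbouring crossings so each
    # stays on its own limb of the trajectory.
    raw <- attr(ps, "raw_interp") %||% d
    b_lo <- config$low_boundary_m
    b_hi <- config$high_boundary_m
    gated <- function(model, fallback, gate_s = 0.35) {
      # The model fit is the most accurate when its assumptions hold but
      # can take a wrong branch; fall back to the re-located crossing when
      # the two disagree by more than the gate.
      if (is.na(model) || abs(model - fallback) > gate_s) fallback else model
    }
    r_up1 <- relocate_crossing(t, d_wide, b_lo, t_up1, "up",
                               lo_s = start, hi_s = (t_up1 + t_up2) / 2)
    turn <- fit_turn_template(t, raw, b_hi, t_up2, t_down2,
                              lo_s = max(t_up2 - 4, (t_up1 + t_up2) / 2),
                              hi_s = min(t_down2 + 4,
                                         (t_down2 + t_down1) / 2))
    if (!is.null(turn)) {
      r_up2 <- turn[1]
      r_down2 <- turn[2]
    } else {
      k_up2 <- fit_kink_crossing(t, raw, b_hi, t_up2,
                                 lo_s = (t_up1 + t_up2) / 2,
                                 hi_s = (t_up2 + t_down2) / 2)
      r_up2 <- gated(k_up2,
                     relocate_crossing(t, d_wide, b_hi, t_up2, "up",
                                       lo_s = (t_up1 + t_up2) / 2,
                                       hi_s = (t_up2 + t_down2) / 2))
      # The down-crossing mirrors the up-crossing; fit on the time-reversed
      # trace so the quadratic term again sits on the turn limb.
      k_down2 <- {
        n <- length(t)
        tr <- t[n] - rev(t)
        k <- fit_kink_crossing(tr, rev(raw), b_hi, t[n] - t_down2,
                               lo_s = t[n] - (t_down2 + t_down1) / 2,
                               hi_s = t[n] - (t_up2 + t_down2) / 2)
        if (is.na(k)) NA_real_ else t[n] - k
      }
      r_down2 <- gated(k_down2,
                       relocate_crossing(t, d_wide, b_hi, t_down2, "down",
                                         lo_s = (t_up2 + t_down2) / 2,
                                         hi_s = (t_down2 + t_down1) / 2))
    }
    r_down1 <- relocate_crossing(t, d_wide, b_lo, t_down1, "down",
                                 lo_s = (t_down2 + t_down1) / 2)
    if (start < r_up1 && r_up1 < r_up2 && r_up2 < r_down2 &&
        r_down2 < r_down1) {
      t_up1 <- r_up1
      t_up2 <- r_up2
      t_down2 <- r_down2
      t_down1 <- r_down1
    }
  }

  endinfo <- tug_detect_end(ps, config, after = t_down1, preprocessed = TRUE)
  end <- endinfo$time

  structure(
    list(sit_up_s = t_up1 - start,
         walk_forward_s = t_up2 - t_up1,
         turn_s = t_down2 - t_up2,
         walk_back_s = t_down1 - t_down2,
         sit_down_s = end - t_down1,
         total_s = end - start,
         boundary_times_s = c(start = start, sit_to_walk = t_up1,
                              walk_to_turn = t_up2, turn_to_walk = t_down2,
                              walk_to_sit = t_down1, end = end),
         truncated = endinfo$truncated),
    class = "subtask_times"
  )
}

#' @export
print.subtask_times <- function(x, ...) {
  cat("TUG subtask times (s):\n")
  v <- unlist(x[c("sit_up_s", "walk_forward_s", "turn_s", "walk_back_s",
                  "sit_down_s", "total_s")])
  print(round(v, 2))
  if (isTRUE(x$truncated)) cat("note: test flagged as truncated\n")
  invisible(x)
}

#' @export
as.data.frame.subtask_times <- function(x, ...) {
  data.frame(sit_up_s = x$sit_up_s, walk_forward_s = x$walk_forward_s,
             turn_s = x$turn_s, walk_back_s = x$walk_back_s,
             sit_down_s = x$sit_down_s, total_s = x$total_s,
             truncated = x$truncated)
}
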