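# Extraction of contractile parameters from TMG displacement traces.
#
# Three parameters summarize a twitch: D_m, the maximal radial displacement
# of the muscle belly; T_d (delay time), from the stimulus to the first
# upward crossing of 10 % of D_m; and T_c (contraction time), from the 10 %
# to the 90 % crossing on the rising limb.  Crossings are located by linear
# interpolation between the straddling samples.

#' Construct a TMG response from raw vectors
#'
#' @param time_ms Timestamps in ms relative to the stimulus at t = 0;
#'   strictly increasing, may include a pre-stimulus baseline window.
#' @param displacement_mm Radial displacement (mm).
#' @param muscle Muscle label, one of `"BF"`, `"GM"`, `"VL"`, `"VM"` (or
#'   `NA`).
#' @param meta Optional identifier list.
#' @return A `tmg_response` object.
#' @export
tmg_response <- function(time_ms, displacement_mm, muscle = NA_character_,
                         meta = NULL) {
  stopifnot(length(time_ms) == length(displacement_mm), length(time_ms) >= 3)
  if (any(diff(time_ms) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (!is.na(muscle) && !muscle %in% c("BF", "GM", "VL", "VM")) {
    stop("`muscle` must be one of BF, GM, VL, VM", call. = FALSE)
  }
  structure(data.frame(time_ms = time_ms, displacement_mm = displacement_mm),
            muscle = muscle, meta = meta,
            class = c("tmg_response", "data.frame"))
}

#' Extract D_m, T_d and T_c from one twitch response
#'
#' The baseline (mean displacement over the pre-stimulus samples, or the
#' first sample if none exist) is subtracted first.  When the trace's noise
#' level exceeds 1 % of the response amplitude, a 3-sample running median is
#' applied before threshold crossings are searched, so isolated noise
#' spikes cannot fake a crossing.
#'
#' @param response A `tmg_response`.
#' @return An object of class `tmg_params`: list with `D_m_mm`, `T_d_ms`,
#'   `T_c_ms`, `muscle` and `n_averaged = 1`.
#' @export
#' @examples
#' tw <- generate_twitch(twitch_truth(amplitude_mm = 5.84))
#' tmg_extract_params(tw)
tmg_extract_params <- function(response) {
  stopifnot(inherits(response, "tmg_response"))
  t <- response$time_ms
  d <- response$displacement_mm
  if (!all(is.finite(d))) stop("non-finite displacement samples", call. = FALSE)
  pre <- t <= 0
  baseline <- if (any(pre)) mean(d[pre]) else d[1]
  d <- d - baseline

  post <- t >= 0
  tp <- t[post]
  dp <- d[post]
  if (length(dp) < 3) stop("trace too short after the stimulus", call. = FALSE)

  # Robust noise estimate from second differences (insensitive to the
  # twitch's own slope); smooth only when needed.
  noise_sd <- stats::mad(diff(diff(dp))) / sqrt(6)
  dm_raw <- max(dp)
  if (dm_raw > 0 && noise_sd > 0.01 * dm_raw && length(dp) > 3) {
    dp <- stats::runmed(dp, 3, endrule = "keep")
  }

  imax <- which.max(dp)
  D_m <- estimate_peak(tp, dp, imax, noise_sd)
  if (!is.finite(D_m) || D_m <= 0) {
    stop("no contraction detected: non-positive response amplitude",
         call. = FALSE)
  }
  if (imax == length(dp)) {
    stop("trace too short: maximum at the final sample", call. = FALSE)
  }
  t10 <- first_crossing_up(tp, dp, 0.10 * D_m, imax)
  t90 <- first_crossing_up(tp, dp, 0.90 * D_m, imax)
  if (is.na(t10) || is.na(t90) || t90 <= t10) {
    stop("numerical degeneracy: amplitude thresholds not crossed in order before the maximum",
         call. = FALSE)
  }
  structure(list(D_m_mm = D_m, T_d_ms = t10, T_c_ms = t90 - t10,
                 muscle = attr(response, "muscle") %||% NA_character_,
                 n_averaged = 1L),
            class = "tmg_params")
}

# Peak amplitude estimate.  The raw max() of a noisy trace is biased
# upwards (it selects the most favourable noise excursion near the flat
# top), and that bias is shared across replicate recordings, so it would
# not average out.  A least-squares parabola over the near-peak window
# gives a vertex estimate that is unbiased under symmetric noise; on a
# noiseless trace the window collapses to the three samples around the
# maximum, where the parabola corrects the curvature bias of max().
estimate_peak <- function(t, d, imax, noise_sd) {
  n <- length(d)
  if (imax == 1L || imax == n) return(d[imax])
  if (noise_sd <= 1e-3 * d[imax]) {
    # Noiseless: a 3-point parabola removes the curvature bias of max().
    denom <- d[imax - 1L] - 2 * d[imax] + d[imax + 1L]
    if (denom < 0) {
      return(d[imax] - (d[imax - 1L] - d[imax + 1L])^2 / (8 * denom))
    }
    return(d[imax])
  }
  # Noisy: least-squares quartic over the upper half-peak region; its
  # maximum is an (essentially) unbiased vertex estimate, unlike max().
  half <- 0.5 * d[imax]
  lo <- imax
  while (lo > 1L && d[lo - 1L] >= half && imax - lo < 20L) lo <- lo - 1L
  hi <- imax
  while (hi < n && d[hi + 1L] >= half && hi - imax < 20L) hi <- hi + 1L
  idx <- lo:hi
  if (length(idx) < 9L) {
    denom <- d[imax - 1L] - 2 * d[imax] + d[imax + 1L]
    if (denom < 0) {
      return(d[imax] - (d[imax - 1L] - d[imax + 1L])^2 / (8 * denom))
    }
    return(d[imax])
  }
  tt <- t[idx] - t[imax]
  span <- max(abs(tt))
  tt <- tt / span
  fit <- stats::.lm.fit(cbind(1, tt, tt^2, tt^3, tt^4), d[idx])
  cf <- fit$coefficients
  if (any(!is.finite(cf))) return(d[imax])
  pk <- stats::optimize(function(u) {
    cf[1] + cf[2] * u + cf[3] * u^2 + cf[4] * u^3 + cf[5] * u^4
  }, range(tt), maximum = TRUE)$objective
  if (!is.finite(pk) || abs(pk - d[imax]) > 4 * noise_sd + 0.1 * d[imax]) {
    return(d[imax])
  }
  pk
}

# First upward crossing of `level` at or before sample `imax`, interpolated.
first_crossing_up <- function(t, d, level, imax) {
  idx <- which(d[seq_len(imax)] >= level)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  if (i == 1L) {
    # Already above the level at the stimulus: degenerate for T_d purposes.
    return(t[1])
  }
  t[i - 1] + (level - d[i - 1]) / (d[i] - d[i - 1]) * (t[i] - t[i - 1])
}

#' Average duplicate TMG responses of one muscle
#'
#' Parameters are extracted per response and then arithmetically averaged
#' (averaging of estimated parameters, not of traces).
#'
#' @param responses A list of `tmg_response` objects from the same muscle.
#' @return A `tmg_params` object with `n_averaged` set to the number of
#'   responses.
#' @export
tmg_average_responses <- function(responses) {
  stopifnot(is.list(responses), length(responses) >= 1)
  muscles <- vapply(responses, function(r) attr(r, "muscle") %||% NA_character_,
                    character(1))
  if (length(unique(muscles)) > 1L) {
    stop(sprintf("mixed muscle labels (%s): responses must come from one muscle",
                 paste(unique(muscles), collapse = ", ")), call. = FALSE)
  }
  per <- lapply(responses, tmg_extract_params)
  structure(list(D_m_mm = mean(vapply(per, `[[`, numeric(1), "D_m_mm")),
                 T_d_ms = mean(vapply(per, `[[`, numeric(1), "T_d_ms")),
                 T_c_ms = mean(vapply(per, `[[`, numeric(1), "T_c_ms")),
                 muscle = muscles[1],
                 n_averaged = length(responses)),
            class = "tmg_params")
}

#' @export
print.tmg_params <- function(x, ...) {
  cat(sprintf("TMG parameters%s: D_m = %.2f mm, T_d = %.2f ms, T_c = %.2f ms (n averaged = %d)\n",
              if (is.na(x$muscle)) "" else paste0(" [", x$muscle, "]"),
              x$D_m_mm, x$T_d_ms, x$T_c_ms, x$n_averaged))
  invisible(x)
}
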