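# Whole-cohort synthesis with a controllable rank-correlation structure.
#
# Participant-level muscle parameters and subtask durations are drawn
# through a Gaussian copula: a multivariate-normal latent score per
# participant, mapped coordinate-wise through inverse CDFs of left-truncated
# normals with the published population moments.  Because Spearman's rho is
# invariant under monotone maps, a rank correlation injected on the latent
# scale (latent Pearson r = 2 sin(pi * rho / 6)) transfers exactly to the
# generated margins.

#' Population moments of the tensiomyography parameters
#'
#' Mean and standard deviation of the contraction time (T_c, ms), delay
#' time (T_d, ms) and maximal displacement (D_m, mm) of the biceps femoris
#' (BF), gastrocnemius medialis (GM), vastus lateralis (VL) and vastus
#' medialis (VM), as observed in the elderly study cohort.
#'
#' @return A `data.frame` with columns `muscle`, `parameter`, `mean`, `sd`.
#' @export
tmg_population_moments <- function() {
  data.frame(
    muscle = rep(c("BF", "GM", "VL", "VM"), each = 3),
    parameter = rep(c("T_c", "T_d", "D_m"), times = 4),
    mean = c(40.79, 30.43, 4.43,
             31.60, 25.82, 2.49,
             29.94, 28.08, 3.74,
             47.22, 29.07, 5.84),
    sd = c(8.79, 5.09, 2.62,
           6.67, 3.72, 1.33,
           8.07, 3.50, 1.68,
           12.16, 3.33, 2.42),
    stringsAsFactors = FALSE
  )
}

#' Population moments of the TUG subtask durations
#'
#' @return A `data.frame` with columns `subtask`, `mean`, `sd` (seconds).
#' @export
tug_population_moments <- function() {
  data.frame(
    subtask = c("sit_up", "walk_forward", "turn", "walk_back", "sit_down"),
    mean = c(4.51, 3.78, 3.00, 4.41, 4.59),
    sd = c(2.12, 1.46, 2.00, 2.58, 2.34),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic study cohort
#'
#' @param n_participants Number of participants (>= 3).
#' @param tests_per_participant TUG tests per participant; a scalar or a
#'   vector of length `n_participants`.  The default 9 reproduces the
#'   study's scale (208 tests over 23 participants).
#' @param tmg_moments,tug_moments Population moments tables, see
#'   [tmg_population_moments()] and [tug_population_moments()].
#' @param target_correlations `NULL` for a fully independent cohort, or a
#'   `data.frame` with columns `parameter` (e.g. `"VM_T_d"`), `subtask`
#'   (e.g. `"sit_up"`) and `rho`, the target population Spearman
#'   correlation (|rho| <= 1) between that muscle parameter and subtask
#'   duration.  Unlisted pairs are independent.
#' @param within_subject_sd_frac Test-to-test variability of each subtask
#'   duration, as a fraction of the between-subject SD.
#' @param noise Sensor [noise_model()] used for the raw TUG signals.
#' @param twitch_noise_sd_mm Additive noise SD of the twitch traces (mm).
#' @param decay_tau_ms Twitch decay time constant shared by all muscles (ms).
#' @param n_twitch_replicates Twitch responses recorded per muscle; the
#'   study protocol records two and averages the estimated parameters.
#' @param sample_rate_hz TUG sampling rate (Hz).
#' @param tmg_sample_rate_hz TMG sampling rate (Hz).
#' @param seed Optional RNG seed for the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 23, tests_per_participant = 9,
                        tmg_moments = tmg_population_moments(),
                        tug_moments = tug_population_moments(),
                        target_correlations = NULL,
                        within_subject_sd_frac = 0.3,
                        noise = noise_model(),
                        twitch_noise_sd_mm = 0.02,
                        decay_tau_ms = 200,
                        n_twitch_replicates = 2,
                        sample_rate_hz = 10,
                        tmg_sample_rate_hz = 1000,
                        seed = NULL) {
  assert_scalar_number(n_participants, "n_participants", lower = 3)
  if (!length(tests_per_participant) %in% c(1L, n_participants) ||
      any(tests_per_participant < 1)) {
    stop("`tests_per_participant` must be a positive scalar or one count per participant",
         call. = FALSE)
  }
  if (!is.null(target_correlations)) {
    stopifnot(is.data.frame(target_correlations),
              all(c("parameter", "subtask", "rho") %in%
                    names(target_correlations)))
    if (any(abs(target_correlations$rho) > 1)) {
      stop("target correlations must satisfy |rho| <= 1", call. = FALSE)
    }
  }
  assert_scalar_number(within_subject_sd_frac, "within_subject_sd_frac",
                       lower = 0)
  stopifnot(inherits(noise, "tug_noise_model"))
  structure(list(n_participants = as.integer(n_participants),
                 tests_per_participant = as.integer(tests_per_participant),
                 tmg_moments = tmg_moments, tug_moments = tug_moments,
                 target_correlations = target_correlations,
                 within_subject_sd_frac = within_subject_sd_frac,
                 noise = noise, twitch_noise_sd_mm = twitch_noise_sd_mm,
                 decay_tau_ms = decay_tau_ms,
                 n_twitch_replicates = as.integer(n_twitch_replicates),
                 sample_rate_hz = sample_rate_hz,
                 tmg_sample_rate_hz = tmg_sample_rate_hz, seed = seed),
            class = "cohort_spec")
}

# Truncation floors for the copula margins.  Clipping at the floor would
# create ties and distort injected rank correlations, so margins are
# left-truncated normals instead.
tmg_param_floor <- function(parameter) {
  switch(parameter, T_c = 5, T_d = 5, D_m = 0.3,
         stop("unknown TMG parameter: ", parameter))
}

#' Generate a synthetic study cohort with known ground truth
#'
#' Draws participant-level muscle parameters and subtask durations through
#' the Gaussian copula described in the package vignette, then materializes
#' the raw recordings: per test a noisy TUG distance signal, per muscle
#' `n_twitch_replicates` noisy twitch traces whose noiseless parameters
#' equal the participant's truth.
#'
#' @param spec A [cohort_spec()].
#' @param materialize `"signals"` (default) generates the raw TUG signals
#'   and TMG traces; `"parameters"` stores only the per-test true durations
#'   and the participant-level parameter truth, which is sufficient for
#'   statistics-level experiments and much faster.
#' @return An object of class `tug_cohort`: a list with `truth`
#'   (participant-level parameter/duration table), `tug_tests` (per-test
#'   table of true durations plus, if materialized, the `tug_signal`
#'   objects), `tmg_traces` (nested list participant > muscle > replicate)
#'   and the `spec`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_participants = 3,
#'                                    tests_per_participant = 1, seed = 1),
#'                        materialize = "parameters")
#' coh$truth[, 1:4]
generate_cohort <- function(spec, materialize = c("signals", "parameters")) {
  stopifnot(inherits(spec, "cohort_spec"))
  materialize <- match.arg(materialize)
  with_rng(spec$seed, generate_cohort_impl(spec, materialize))
}

generate_cohort_impl <- function(spec, materialize) {
  n <- spec$n_participants
  tm <- spec$tmg_moments
  um <- spec$tug_moments
  param_names <- paste(tm$muscle, tm$parameter, sep = "_")
  subtask_names <- um$subtask
  vars <- c(param_names, subtask_names)
  p <- length(vars)

  # Latent correlation matrix with the Spearman targets converted to the
  # equivalent bivariate-normal Pearson correlation.
  R <- diag(p)
  tc <- spec$target_correlations
  for (q in seq_len(NROW(tc))) {
    i <- match(tc$parameter[q], vars)
    j <- match(tc$subtask[q], vars)
    if (is.na(i) || is.na(j)) {
      stop(sprintf("unknown pair in target_correlations: %s / %s",
                   tc$parameter[q], tc$subtask[q]), call. = FALSE)
    }
    R[i, j] <- R[j, i] <- 2 * sin(pi * tc$rho[q] / 6)
  }
  ch <- tryCatch(chol(R), error = function(e) {
    stop("infeasible correlation set: the copula correlation matrix is not positive definite",
         call. = FALSE)
  })
  Z <- matrix(stats::rnorm(n * p), n, p) %*% ch
  U <- stats::pnorm(Z)
  colnames(U) <- vars

  truth <- data.frame(participant_id = sprintf("P%02d", seq_len(n)))
  for (q in seq_len(nrow(tm))) {
    truth[[param_names[q]]] <- qnorm_truncated(
      U[, param_names[q]], tm$mean[q], tm$sd[q],
      floor = tmg_param_floor(tm$parameter[q]))
  }
  for (q in seq_len(nrow(um))) {
    truth[[subtask_names[q]]] <- qnorm_truncated(
      U[, subtask_names[q]], um$mean[q], um$sd[q],
      floor = min_subtask_duration_s())
  }

  tests_per <- rep_len(spec$tests_per_participant, n)
  tug_rows <- vector("list", sum(tests_per))
  signals <- if (materialize == "signals") vector("list", sum(tests_per))
  row <- 0L
  for (i in seq_len(n)) {
    for (k in seq_len(tests_per[i])) {
      row <- row + 1L
      dur <- pmax(as.numeric(truth[i, subtask_names]) +
                    stats::rnorm(length(subtask_names), 0,
                                 spec$within_subject_sd_frac * um$sd),
                  min_subtask_duration_s())
      prof <- tug_profile(sit_up_s = dur[1], walk_forward_s = dur[2],
                          turn_s = dur[3], walk_back_s = dur[4],
                          sit_down_s = dur[5],
                          turn_apex_m = stats::runif(1, 3.30, 3.50))
      if (materialize == "signals") {
        signals[[row]] <- generate_tug_signal(prof, spec$noise,
                                              spec$sample_rate_hz)
      }
      tug_rows[[row]] <- data.frame(
        participant_id = truth$participant_id[i], test = k,
        sit_up_s = dur[1], walk_forward_s = dur[2], turn_s = dur[3],
        walk_back_s = dur[4], sit_down_s = dur[5], total_s = sum(dur))
    }
  }
  tug_tests <- do.call(rbind, tug_rows)

  tmg_traces <- NULL
  if (materialize == "signals") {
    muscles <- unique(tm$muscle)
    tmg_traces <- lapply(seq_len(n), function(i) {
      per_muscle <- lapply(muscles, function(m) {
        shape <- solve_twitch_shape(
          tc_ms = truth[[paste0(m, "_T_c")]][i],
          td_ms = truth[[paste0(m, "_T_d")]][i],
          decay_tau_ms = spec$decay_tau_ms)
        lapply(seq_len(spec$n_twitch_replicates), function(r) {
          generate_twitch(
            twitch_truth(amplitude_mm = truth[[paste0(m, "_D_m")]][i],
                         latency_ms = shape$latency_ms,
                         rise_tau_ms = shape$rise_tau_ms,
                         decay_tau_ms = shape$decay_tau_ms,
                         sample_rate_hz = spec$tmg_sample_rate_hz,
                         noise_sd_mm = spec$twitch_noise_sd_mm),
            muscle = m, oracle = FALSE)
        })
      })
      names(per_muscle) <- muscles
      per_muscle
    })
    names(tmg_traces) <- truth$participant_id
  }

  structure(list(truth = truth, tug_tests = tug_tests, signals = signals,
                 tmg_traces = tmg_traces, spec = spec,
                 materialized = materialize),
            class = "tug_cohort")
}

#' @export
print.tug_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TUG/TMG cohort: %d participants, %d TUG tests, %s\n",
              nrow(x$truth), nrow(x$tug_tests),
              if (x$materialized == "signals")
                sprintf("%d TMG traces",
                        sum(lengths(lapply(x$tmg_traces, unlist,
                                           recursive = FALSE))))
              else "parameters only"))
  invisible(x)
}

#' Run the measurement chain over a synthetic cohort
#'
#' Applies [tug_segment()] to every materialized TUG signal and
#' [tmg_average_responses()] to every muscle's twitch replicates, producing
#' the per-test and per-muscle measurement tables the statistics layer
#' consumes.  For a parameters-only cohort the stored true values are
#' passed through unchanged.
#'
#' @param cohort A `tug_cohort` from [generate_cohort()].
#' @param config A [band_config()] for segmentation.
#' @return A list with `tug` (one row per segmented test), `tmg` (one row
#'   per participant and muscle) and `log` (per-recording failures, if
#'   any).
#' @export
measure_cohort <- function(cohort, config = band_config()) {
  stopifnot(inherits(cohort, "tug_cohort"))
  log <- list()
  if (cohort$materialized != "signals") {
    tm <- cohort$spec$tmg_moments
    param_names <- paste(tm$muscle, tm$parameter, sep = "_")
    tmg <- do.call(rbind, lapply(unique(tm$muscle), function(m) {
      data.frame(participant_id = cohort$truth$participant_id, muscle = m,
                 T_c_ms = cohort$truth[[paste0(m, "_T_c")]],
                 T_d_ms = cohort$truth[[paste0(m, "_T_d")]],
                 D_m_mm = cohort$truth[[paste0(m, "_D_m")]],
                 n_averaged = 1L)
    }))
    return(list(tug = cohort$tug_tests, tmg = tmg, log = log))
  }

  tug_rows <- vector("list", length(cohort$signals))
  for (q in seq_along(cohort$signals)) {
    res <- tryCatch(tug_segment(cohort$signals[[q]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      log[[length(log) + 1L]] <- list(
        what = "tug", participant_id = cohort$tug_tests$participant_id[q],
        test = cohort$tug_tests$test[q], reason = conditionMessage(res))
      next
    }
    tug_rows[[q]] <- cbind(cohort$tug_tests[q, c("participant_id", "test")],
                           as.data.frame(res))
  }
  tug <- do.call(rbind, tug_rows)

  tmg_rows <- list()
  for (pid in names(cohort$tmg_traces)) {
    for (m in names(cohort$tmg_traces[[pid]])) {
      res <- tryCatch(tmg_average_responses(cohort$tmg_traces[[pid]][[m]]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        log[[length(log) + 1L]] <- list(what = "tmg", participant_id = pid,
                                        muscle = m,
                                        reason = conditionMessage(res))
        next
      }
      tmg_rows[[length(tmg_rows) + 1L]] <- data.frame(
        participant_id = pid, muscle = m, T_c_ms = res$T_c_ms,
        T_d_ms = res$T_d_ms, D_m_mm = res$D_m_mm,
        n_averaged = res$n_averaged)
    }
  }
  tmg <- do.call(rbind, tmg_rows)
  rownames(tug) <- rownames(tmg) <- NULL
  list(tug = tug, tmg = tmg, log = log)
}
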