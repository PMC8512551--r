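# Participant aggregation, Spearman correlation and the descriptive /
# correlation tables with raw and Bonferroni-adjusted significance flags.

tug_time_cols <- function() c("sit_up_s", "walk_forward_s", "turn_s",
                              "walk_back_s", "sit_down_s", "total_s")

#' Aggregate measurements into per-participant records
#'
#' Computes the arithmetic mean of each of the six TUG times across a
#' participant's tests and of each muscle parameter across their TMG
#' sessions.  Only participants with at least one TUG and one TMG
#' measurement are eligible; the rest are excluded and listed in the
#' `excluded` attribute.
#'
#' @param tug `data.frame` with one row per test: `participant_id` plus the
#'   six duration columns (`sit_up_s`, `walk_forward_s`, `turn_s`,
#'   `walk_back_s`, `sit_down_s`, `total_s`).
#' @param tmg `data.frame` with one row per session and muscle:
#'   `participant_id`, `muscle`, `T_c_ms`, `T_d_ms`, `D_m_mm`.
#' @return A `data.frame` with one row per eligible participant:
#'   `participant_id`, the six mean TUG times and the twelve mean muscle
#'   parameters (columns like `VM_T_d`).  Attribute `excluded` is a
#'   `data.frame` of excluded participants with reasons.
#' @export
build_participant_records <- function(tug, tmg) {
  stopifnot(is.data.frame(tug), is.data.frame(tmg))
  need <- c("participant_id", tug_time_cols())
  if (!all(need %in% names(tug))) {
    stop("`tug` is missing column(s): ",
         paste(setdiff(need, names(tug)), collapse = ", "), call. = FALSE)
  }
  need <- c("participant_id", "muscle", "T_c_ms", "T_d_ms", "D_m_mm")
  if (!all(need %in% names(tmg))) {
    stop("`tmg` is missing column(s): ",
         paste(setdiff(need, names(tmg)), collapse = ", "), call. = FALSE)
  }
  tug_ids <- unique(tug$participant_id)
  tmg_ids <- unique(tmg$participant_id)
  eligible <- intersect(tug_ids, tmg_ids)
  no_tmg <- setdiff(tug_ids, tmg_ids)
  no_tug <- setdiff(tmg_ids, tug_ids)
  excl <- data.frame(
    participant_id = c(no_tmg, no_tug),
    reason = c(rep("no TMG measurement", length(no_tmg)),
               rep("no TUG measurement", length(no_tug)))
  )
  if (length(eligible) == 0L) {
    stop("no eligible participants: none has both a TUG and a TMG measurement",
         call. = FALSE)
  }
  tug_mean <- stats::aggregate(tug[tug_time_cols()],
                               by = list(participant_id = tug$participant_id),
                               FUN = mean)
  out <- tug_mean[tug_mean$participant_id %in% eligible, , drop = FALSE]
  for (m in c("BF", "GM", "VL", "VM")) {
    sub <- tmg[tmg$muscle == m, , drop = FALSE]
    if (nrow(sub) == 0L) next
    agg <- stats::aggregate(sub[c("T_c_ms", "T_d_ms", "D_m_mm")],
                            by = list(participant_id = sub$participant_id),
                            FUN = mean)
    idx <- match(out$participant_id, agg$participant_id)
    out[[paste0(m, "_T_c")]] <- agg$T_c_ms[idx]
    out[[paste0(m, "_T_d")]] <- agg$T_d_ms[idx]
    out[[paste0(m, "_D_m")]] <- agg$D_m_mm[idx]
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excl
  out
}

# --- Spearman correlation ---------------------------------------------------

# Cache of permutation index matrices, keyed by n.
.perm_cache <- new.env(parent = emptyenv())

# All n! permutations of 1..n as an n! x n integer matrix.
perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  out <- if (n == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- perm_matrix(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(rep(k, nrow(sub)), sub + (sub >= k))
    }))
  }
  storage.mode(out) <- "integer"
  .perm_cache[[key]] <- out
  out
}

#' Spearman rank correlation with an exact small-sample p-value
#'
#' The coefficient is the Pearson correlation of the average ranks (ties
#' receive average ranks).  For `n > 9` the p-value uses the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom; for `n <= 9` the exact permutation distribution over all
#' `n!` rank assignments is enumerated.  Both p-values are two-sided.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, finite.
#' @param exact `NULL` (choose by the `n <= 9` rule) or a logical forcing
#'   the permutation / t path.
#' @return A list with `rho`, `p_value`, `n` and `method`.
#' @export
#' @examples
#' spearman_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
spearman_test <- function(x, y, exact = NULL) {
  stopifnot(length(x) == length(y))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: zero rank variance", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (is.null(exact)) exact <- n <= 9
  if (exact) {
    P <- perm_matrix(n)
    # Pearson-on-ranks for every permutation via the cross-product
    # statistic T = sum(rx * ry[perm]).
    Tv <- matrix(ry[P], nrow(P), n) %*% rx
    mu <- n * mean(rx) * mean(ry)
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rho_all <- (as.numeric(Tv) - mu) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-8)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Bonferroni-adjusted significance threshold
#'
#' Divides the significance level by the family size.  With the study's
#' family of 12 muscle parameters this gives 0.05 / 12, reported as 0.0042
#' after rounding to four decimals.
#'
#' @param alpha Raw significance level, in (0, 1).
#' @param k Family size, >= 1.
#' @return `alpha / k` (unrounded).
#' @export
#' @examples
#' round(bonferroni_threshold(0.05, 12), 4)
bonferroni_threshold <- function(alpha, k) {
  assert_scalar_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  if (alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  assert_scalar_number(k, "k", lower = 1)
  alpha / k
}

#' Spearman correlation table of muscle parameters against subtask times
#'
#' Computes the Spearman correlation and p-value for every pair of the 12
#' muscle parameters (4 muscles x T_c, T_d, D_m) and the 6 TUG times (5
#' subtasks plus the total), with significance flags at the raw level and
#' at the Bonferroni-adjusted level `alpha / family_size`.  Cells whose
#' correlation is undefined are reported as `NA`, never fabricated.
#'
#' @param records Per-participant records from
#'   [build_participant_records()].
#' @param alpha Raw significance level.
#' @param family_size Bonferroni family size; the default 12 counts the
#'   muscle-parameter family.
#' @return A `data.frame` with one row per pair: `muscle`, `parameter`,
#'   `tug_time`, `rho`, `p_value`, `n`, `sig_raw`, `sig_adj` and a `note`
#'   for failed cells.  Attribute `adjusted_alpha` holds the threshold.
#' @export
correlation_table <- function(records, alpha = 0.05, family_size = 12) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 3) {
    stop("need at least 3 participant records", call. = FALSE)
  }
  adj <- bonferroni_threshold(alpha, family_size)
  rows <- list()
  for (m in c("BF", "GM", "VL", "VM")) {
    for (pp in c("T_c", "T_d", "D_m")) {
      pcol <- paste0(m, "_", pp)
      for (tcol in tug_time_cols()) {
        res <- tryCatch(spearman_test(records[[pcol]], records[[tcol]]),
                        error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            muscle = m, parameter = pp, tug_time = tcol, rho = NA_real_,
            p_value = NA_real_, n = nrow(records), sig_raw = NA,
            sig_adj = NA, note = conditionMessage(res))
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            muscle = m, parameter = pp, tug_time = tcol, rho = res$rho,
            p_value = res$p_value, n = res$n,
            sig_raw = res$p_value < alpha, sig_adj = res$p_value < adj,
            note = NA_character_)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "adjusted_alpha") <- adj
  out
}

#' Descriptive statistics table (mean, SD, min, max)
#'
#' Summarizes every muscle parameter and TUG time as mean, sample standard
#' deviation (n - 1 denominator), minimum and maximum.  By default the
#' statistics pool all measurements (every test and session); set
#' `granularity = "participant"` to summarize participant means instead.
#'
#' @inheritParams build_participant_records
#' @param granularity `"pooled"` or `"participant"`.
#' @return A `data.frame` with columns `variable`, `mean`, `sd`, `min`,
#'   `max`, `n`.  Single-observation variables report `sd = NA`.
#' @export
descriptive_table <- function(tug, tmg,
                              granularity = c("pooled", "participant")) {
  granularity <- match.arg(granularity)
  if (granularity == "participant") {
    rec <- build_participant_records(tug, tmg)
    vals <- c(
      lapply(stats::setNames(nm = grep("^(BF|GM|VL|VM)_", names(rec),
                                       value = TRUE)),
             function(cl) rec[[cl]]),
      lapply(stats::setNames(nm = tug_time_cols()), function(cl) rec[[cl]])
    )
  } else {
    vals <- list()
    for (m in c("BF", "GM", "VL", "VM")) {
      sub <- tmg[tmg$muscle == m, , drop = FALSE]
      vals[[paste0(m, "_T_c")]] <- sub$T_c_ms
      vals[[paste0(m, "_T_d")]] <- sub$T_d_ms
      vals[[paste0(m, "_D_m")]] <- sub$D_m_mm
    }
    for (cl in tug_time_cols()) vals[[cl]] <- tug[[cl]]
  }
  rows <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    v <- v[is.finite(v)]
    data.frame(variable = nm,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               n = length(v))
  })
  do.call(rbind, rows)
}

#' Export scatter and boxplot data for significant correlations
#'
#' For every raw-significant pair of the correlation table, writes a CSV of
#' the participant-level (x, y) points; an accompanying
#' `regression_lines.csv` holds the ordinary-least-squares slope and
#' intercept used to annotate scatter plots.  Per-subtask boxplot quartiles
#' (min, lower quartile, median, upper quartile, max) go to
#' `boxplot_quartiles.csv`.
#'
#' @param records Per-participant records.
#' @param table A [correlation_table()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
export_plot_data <- function(records, table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  sig <- table[!is.na(table$sig_raw) & table$sig_raw, , drop = FALSE]
  reg_rows <- list()
  for (q in seq_len(nrow(sig))) {
    pcol <- paste0(sig$muscle[q], "_", sig$parameter[q])
    tcol <- sig$tug_time[q]
    df <- data.frame(participant_id = records$participant_id,
                     x = records[[pcol]], y = records[[tcol]])
    fit <- stats::lm(y ~ x, data = df)
    path <- file.path(dir, sprintf("scatter_%s_%s.csv", pcol, tcol))
    utils::write.csv(df, path, row.names = FALSE)
    written <- c(written, path)
    reg_rows[[q]] <- data.frame(parameter = pcol, tug_time = tcol,
                                slope = unname(stats::coef(fit)[2]),
                                intercept = unname(stats::coef(fit)[1]),
                                n = nrow(df))
  }
  if (length(reg_rows)) {
    path <- file.path(dir, "regression_lines.csv")
    utils::write.csv(do.call(rbind, reg_rows), path, row.names = FALSE)
    written <- c(written, path)
  }
  box_rows <- lapply(tug_time_cols(), function(cl) {
    qs <- stats::quantile(records[[cl]], c(0, 0.25, 0.5, 0.75, 1),
                          names = FALSE)
    data.frame(tug_time = cl, min = qs[1], q1 = qs[2], median = qs[3],
               q3 = qs[4], max = qs[5])
  })
  path <- file.path(dir, "boxplot_quartiles.csv")
  utils::write.csv(do.call(rbind, box_rows), path, row.names = FALSE)
  written <- c(written, path)
  invisible(written)
}
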