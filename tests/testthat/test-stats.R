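make_records <- function(n = 12, seed = 1) {
  # Independent records with plausible scales, one row per participant.
  withr::with_seed(seed, {
    rec <- data.frame(participant_id = sprintf("P%02d", seq_len(n)))
    for (m in c("BF", "GM", "VL", "VM")) {
      rec[[paste0(m, "_T_c")]] <- rnorm(n, 40, 8)
      rec[[paste0(m, "_T_d")]] <- rnorm(n, 28, 4)
      rec[[paste0(m, "_D_m")]] <- rnorm(n, 4, 1.5)
    }
    for (cl in c("sit_up_s", "walk_forward_s", "turn_s", "walk_back_s",
                 "sit_down_s")) {
      rec[[cl]] <- rlnorm(n, 1.3, 0.4)
    }
    rec$total_s <- rec$sit_up_s + rec$walk_forward_s + rec$turn_s +
      rec$walk_back_s + rec$sit_down_s
    rec
  })
}

test_that("perfectly monotone pairs give rho of plus and minus one", {
  expect_equal(spearman_test(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_test(1:4, c(8, 7, 6, 5))$rho, -1)
})

test_that("exact permutation results equal exhaustive enumeration", {
  res <- spearman_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  orc <- spearman_brute(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(res$rho, orc$rho, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p_value, tolerance = 1e-12)
  expect_identical(res$method, "exact permutation")
  withr::local_seed(55)
  for (r in 1:20) {
    n <- sample(3:7, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    res <- spearman_test(x, y)
    orc <- spearman_brute(x, y)
    expect_equal(res$rho, orc$rho, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p_value, tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly increasing transforms", {
  withr::local_seed(8)
  x <- rnorm(15)
  y <- rnorm(15)
  base <- spearman_test(x, y)
  expect_equal(spearman_test(exp(x), y)$rho, base$rho)
  expect_equal(spearman_test(x, y^3 + 5 * y)$rho, base$rho)
  expect_equal(spearman_test(exp(x), y^3 + 5 * y)$p_value, base$p_value)
})

test_that("the t-approximation agrees with the reference implementation", {
  withr::local_seed(12)
  x <- rnorm(23)
  y <- rnorm(23)
  res <- spearman_test(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  # cor.test uses the AS89/exact machinery; the t approximation must agree
  # with the directly computed t reference
  tstat <- res$rho * sqrt((23 - 2) / (1 - res$rho^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), 21))
})

test_that("degenerate inputs are rejected", {
  expect_error(spearman_test(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  expect_error(spearman_test(1:2, 2:3), "at least 3")
  expect_error(spearman_test(c(1, 2, NA), c(1, 2, 3)), "finite")
})

test_that("the Bonferroni threshold reproduces the published 0.0042", {
  expect_equal(round(bonferroni_threshold(0.05, 12), 4), 0.0042)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 72), 0.000694, tolerance = 1e-3)
  expect_error(bonferroni_threshold(0.05, 0), "k")
  expect_error(bonferroni_threshold(1.2, 12), "alpha")
})

test_that("participant records are arithmetic means with exclusions logged", {
  tug <- data.frame(participant_id = c("A", "A", "B"),
                    sit_up_s = c(4, 6, 5), walk_forward_s = c(3, 5, 4),
                    turn_s = c(2, 4, 3), walk_back_s = c(4, 6, 5),
                    sit_down_s = c(5, 1, 3), total_s = c(18, 22, 20))
  tmg <- data.frame(participant_id = c("A", "C"), muscle = "VM",
                    T_c_ms = c(40, 50), T_d_ms = c(28, 30),
                    D_m_mm = c(5, 6))
  rec <- build_participant_records(tug, tmg)
  expect_identical(rec$participant_id, "A")
  expect_equal(rec$total_s, 20)
  excl <- attr(rec, "excluded")
  expect_setequal(excl$participant_id, c("B", "C"))
  expect_error(build_participant_records(tug[0, ], tmg), "eligible")
})

test_that("the correlation table covers all 72 pairs with nested flags", {
  rec <- make_records(12)
  tab <- correlation_table(rec, alpha = 0.05, family_size = 12)
  expect_identical(nrow(tab), 72L)
  expect_true(all(abs(tab$rho) <= 1, na.rm = TRUE))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  # threshold nesting: adjusted significance implies raw significance
  expect_true(all(!tab$sig_adj | tab$sig_raw, na.rm = TRUE))
  expect_lte(sum(tab$sig_adj, na.rm = TRUE), sum(tab$sig_raw, na.rm = TRUE))
  expect_equal(attr(tab, "adjusted_alpha"), 0.05 / 12)
})

test_that("failed correlation cells are reported as missing", {
  rec <- make_records(12)
  rec$BF_T_c <- 1  # zero rank variance
  tab <- correlation_table(rec)
  bad <- tab[tab$muscle == "BF" & tab$parameter == "T_c", ]
  expect_true(all(is.na(bad$rho)))
  expect_true(all(grepl("zero rank variance", bad$note)))
  good <- tab[!(tab$muscle == "BF" & tab$parameter == "T_c"), ]
  expect_true(all(!is.na(good$rho)))
})

test_that("descriptive statistics match direct computation", {
  tug <- data.frame(participant_id = c("A", "A", "B"),
                    sit_up_s = c(4, 6, 5), walk_forward_s = c(3, 5, 4),
                    turn_s = c(2, 4, 3), walk_back_s = c(4, 6, 5),
                    sit_down_s = c(5, 1, 3), total_s = c(9.76, 48.67, 20))
  tmg <- data.frame(participant_id = c("A", "B"), muscle = "VM",
                    T_c_ms = c(40, 50), T_d_ms = c(28, 30),
                    D_m_mm = c(5, 6))
  tab <- descriptive_table(tug, tmg)
  tot <- tab[tab$variable == "total_s", ]
  expect_equal(tot$min, 9.76)
  expect_equal(tot$max, 48.67)
  expect_equal(tot$mean, mean(c(9.76, 48.67, 20)))
  expect_equal(tot$sd, sd(c(9.76, 48.67, 20)))
  # a single observation has no sample SD
  tmg1 <- tmg[1, ]
  tab1 <- descriptive_table(tug, tmg1)
  expect_true(is.na(tab1$sd[tab1$variable == "VM_T_c"]))
  expect_identical(tab1$n[tab1$variable == "VM_T_c"], 1L)
})

test_that("plot-data export writes one scatter file per significant pair", {
  rec <- make_records(12, seed = 3)
  # inject a strong association so at least one pair is significant
  rec$VM_T_d <- rec$sit_up_s * 2 + rnorm(12, 0, 0.01)
  tab <- correlation_table(rec)
  dir <- withr::local_tempdir()
  files <- export_plot_data(rec, tab, dir)
  n_sig <- sum(tab$sig_raw, na.rm = TRUE)
  expect_gte(n_sig, 1)
  scatter <- list.files(dir, pattern = "^scatter_")
  expect_length(scatter, n_sig)
  one <- utils::read.csv(file.path(dir, scatter[1]))
  expect_identical(nrow(one), 12L)
  expect_true(file.exists(file.path(dir, "boxplot_quartiles.csv")))
  # no significant pairs -> no scatter files
  rec0 <- make_records(12, seed = 4)
  tab0 <- correlation_table(rec0)
  tab0$sig_raw <- FALSE
  dir0 <- withr::local_tempdir()
  export_plot_data(rec0, tab0, dir0)
  expect_length(list.files(dir0, pattern = "^scatter_"), 0)
})

test_that("OLS annotation recovers an exact linear relationship", {
  rec <- make_records(12, seed = 5)
  rec$VM_T_d <- 1:12
  rec$sit_up_s <- 1:12  # slope 1, intercept 0
  tab <- correlation_table(rec)
  dir <- withr::local_tempdir()
  export_plot_data(rec, tab, dir)
  reg <- utils::read.csv(file.path(dir, "regression_lines.csv"))
  row <- reg[reg$parameter == "VM_T_d" & reg$tug_time == "sit_up_s", ]
  expect_equal(row$slope, 1, tolerance = 1e-9)
  expect_equal(row$intercept, 0, tolerance = 1e-9)
})
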