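test_that("twitch oracle values satisfy the basic identities", {
  tw <- generate_twitch(twitch_truth(amplitude_mm = 5.84, latency_ms = 10,
                                     rise_tau_ms = 20, decay_tau_ms = 200))
  orc <- attr(tw, "truth")$oracle
  expect_equal(orc$D_m_mm, 5.84)
  expect_gt(orc$T_d_ms, 0)
  expect_gt(orc$T_c_ms, 0)
  expect_lt(orc$T_d_ms + orc$T_c_ms, max(tw$time_ms))
  # trace maximum equals the target amplitude within 0.1 %
  expect_equal(max(tw$displacement_mm), 5.84, tolerance = 1e-3)
  # trace long enough to cover the decay
  expect_gte(max(tw$time_ms), 5 * 200)
  expect_true(all(tw$displacement_mm >= 0))
})

test_that("vanishing rise time drives the delay time to the latency", {
  tw <- generate_twitch(twitch_truth(amplitude_mm = 1, latency_ms = 0,
                                     rise_tau_ms = 0.01, decay_tau_ms = 50))
  expect_lt(attr(tw, "truth")$oracle$T_d_ms, 0.5)
})

test_that("invalid twitch parameters are rejected", {
  expect_error(twitch_truth(amplitude_mm = 0), "amplitude_mm")
  expect_error(twitch_truth(amplitude_mm = 1, rise_tau_ms = 30,
                            decay_tau_ms = 20), "decay_tau_ms")
  expect_error(twitch_truth(amplitude_mm = NaN), "amplitude_mm")
})

test_that("seeded twitch noise is reproducible", {
  tt <- twitch_truth(amplitude_mm = 3, noise_sd_mm = 0.05, seed = 11)
  expect_identical(generate_twitch(tt)$displacement_mm,
                   generate_twitch(tt)$displacement_mm)
})

test_that("a linear ramp yields the analytic parameters", {
  t <- 0:1100
  d <- pmin(2 * t / 1000, 2)
  p <- tmg_extract_params(tmg_response(t, d))
  expect_equal(p$D_m_mm, 2, tolerance = 1e-3)
  expect_equal(p$T_d_ms, 100, tolerance = 0.2)
  expect_equal(p$T_c_ms, 800, tolerance = 0.2)
})

test_that("extraction matches the dense-grid oracle on noiseless twitches", {
  withr::local_seed(204)
  for (r in 1:25) {
    A <- runif(1, 0.5, 12)
    rise <- runif(1, 5, 60)
    tw <- generate_twitch(twitch_truth(A, runif(1, 0, 30), rise,
                                       rise * runif(1, 3, 12)))
    orc <- attr(tw, "truth")$oracle
    p <- tmg_extract_params(tw)
    expect_equal(p$D_m_mm, orc$D_m_mm, tolerance = 0.01 / orc$D_m_mm)
    expect_lt(abs(p$T_d_ms - orc$T_d_ms), 0.5)
    expect_lt(abs(p$T_c_ms - orc$T_c_ms), 0.5)
  }
})

test_that("a flat trace raises the no-contraction error", {
  expect_error(tmg_extract_params(tmg_response(0:100, rep(0, 101))),
               "no contraction")
})

test_that("a nonzero baseline is subtracted before thresholding", {
  tw <- generate_twitch(twitch_truth(amplitude_mm = 4))
  shifted <- tmg_response(tw$time_ms, tw$displacement_mm + 1.5)
  p0 <- tmg_extract_params(tw)
  p1 <- tmg_extract_params(shifted)
  expect_equal(p1$D_m_mm, p0$D_m_mm, tolerance = 1e-6)
  expect_equal(p1$T_d_ms, p0$T_d_ms, tolerance = 1e-6)
})

test_that("amplitude scaling scales D_m and leaves the times unchanged", {
  tw <- generate_twitch(twitch_truth(amplitude_mm = 3))
  k <- 2.5
  scaled <- tmg_response(tw$time_ms, tw$displacement_mm * k)
  p <- tmg_extract_params(tw)
  ps <- tmg_extract_params(scaled)
  expect_equal(ps$D_m_mm, k * p$D_m_mm, tolerance = 1e-9)
  expect_equal(ps$T_d_ms, p$T_d_ms, tolerance = 1e-9)
  expect_equal(ps$T_c_ms, p$T_c_ms, tolerance = 1e-9)
})

test_that("time stretching scales the times and leaves D_m unchanged", {
  tw <- generate_twitch(twitch_truth(amplitude_mm = 3))
  k <- 1.7
  stretched <- tmg_response(tw$time_ms * k, tw$displacement_mm)
  p <- tmg_extract_params(tw)
  ps <- tmg_extract_params(stretched)
  expect_equal(ps$D_m_mm, p$D_m_mm, tolerance = 1e-9)
  expect_equal(ps$T_d_ms, k * p$T_d_ms, tolerance = 1e-6)
  expect_equal(ps$T_c_ms, k * p$T_c_ms, tolerance = 1e-6)
})

test_that("the thresholds are crossed before the maximum", {
  withr::local_seed(17)
  for (r in 1:10) {
    tw <- generate_twitch(twitch_truth(runif(1, 1, 8), runif(1, 5, 30),
                                       runif(1, 10, 40), runif(1, 150, 300),
                                       noise_sd_mm = 0.02))
    p <- tmg_extract_params(tw)
    tmax <- tw$time_ms[which.max(tw$displacement_mm)]
    expect_lt(p$T_d_ms, p$T_d_ms + p$T_c_ms)
    expect_lte(p$T_d_ms + p$T_c_ms, tmax + 1)
  }
})

test_that("averaging is the arithmetic mean of per-response parameters", {
  tw <- generate_twitch(twitch_truth(amplitude_mm = 4), muscle = "VM")
  single <- tmg_extract_params(tw)
  avg <- tmg_average_responses(list(tw, tw))
  expect_equal(avg$D_m_mm, single$D_m_mm)
  expect_equal(avg$T_c_ms, single$T_c_ms)
  expect_identical(avg$n_averaged, 2L)
  # 40 and 42 ms contraction times average to 41 ms
  a <- generate_twitch(twitch_truth(4, 10, 20, 200), muscle = "VM")
  b <- tmg_response(a$time_ms * (tmg_extract_params(a)$T_c_ms + 2) /
                      tmg_extract_params(a)$T_c_ms,
                    a$displacement_mm, muscle = "VM")
  pa <- tmg_extract_params(a)
  pb <- tmg_extract_params(b)
  avg2 <- tmg_average_responses(list(a, b))
  expect_equal(avg2$T_c_ms, (pa$T_c_ms + pb$T_c_ms) / 2)
})

test_that("mixed muscle labels are rejected", {
  a <- generate_twitch(twitch_truth(4), muscle = "VM")
  b <- generate_twitch(twitch_truth(4), muscle = "BF")
  expect_error(tmg_average_responses(list(a, b)), "mixed muscle")
})

test_that("averaging two noisy replicates usually beats a single extraction", {
  withr::local_seed(88)
  sh <- tugtmg:::twitch_shape(20, 200)
  t10 <- tugtmg:::twitch_rise_crossing(sh, 0.1)
  t90 <- tugtmg:::twitch_rise_crossing(sh, 0.9)
  truth <- c(5.84, 25 + t10, t90 - t10)
  better <- 0
  n_mc <- 200
  for (r in seq_len(n_mc)) {
    tr1 <- generate_twitch(twitch_truth(5.84, 25, 20, 200,
                                        noise_sd_mm = 0.05), oracle = FALSE)
    tr2 <- generate_twitch(twitch_truth(5.84, 25, 20, 200,
                                        noise_sd_mm = 0.05), oracle = FALSE)
    p1 <- tmg_extract_params(tr1)
    pa <- tmg_average_responses(list(tr1, tr2))
    e1 <- c(p1$D_m_mm, p1$T_d_ms, p1$T_c_ms) - truth
    ea <- c(pa$D_m_mm, pa$T_d_ms, pa$T_c_ms) - truth
    if (sum(ea^2) < sum(e1^2)) better <- better + 1
  }
  expect_gte(better / n_mc, 0.6)
})

test_that("twitch shapes can be solved back from target parameters", {
  sol <- tugtmg:::solve_twitch_shape(tc_ms = 47.22, td_ms = 29.07)
  tw <- generate_twitch(twitch_truth(5.84, sol$latency_ms, sol$rise_tau_ms,
                                     sol$decay_tau_ms))
  orc <- attr(tw, "truth")$oracle
  expect_equal(orc$T_c_ms, 47.22, tolerance = 1e-3)
  expect_equal(orc$T_d_ms, 29.07, tolerance = 1e-3)
  expect_error(tugtmg:::solve_twitch_shape(tc_ms = 500, td_ms = 30),
               "not attainable")
})
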