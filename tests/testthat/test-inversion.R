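test_that("the default grid reproduces the standard search lattice", {
  g <- inversion_grid()
  expect_length(g$conc, 1501)
  expect_length(g$time, 601)
  expect_identical(g$conc[2] - g$conc[1], 12)
  expect_equal(g$time[2] - g$time[1], 0.05)
  expect_error(inversion_grid(conc_step = 0), "positive")
  expect_error(inversion_grid(time_max = -1), ">= minima")
})

test_that("the squared-error objective matches hand arithmetic", {
  expect_identical(sse_objective(1.0, 2.0, 1.0, 2.0), 0)
  expect_identical(sse_objective(1.0, 2.0, 1.0, 1.0), 1.0)
  # the time-zero objective for a (0.48, 2.7) measurement pair
  expect_equal(sse_objective(0.48, 2.7, 0, 0), 7.5204)
  # symmetric in the sign of each residual
  expect_equal(sse_objective(1, 2, 1.3, 2.4), sse_objective(1, 2, 0.7, 1.6))
  expect_error(sse_objective(-1, 2, 0, 0), "non-negative")
  expect_error(sse_objective(NA_real_, 2, 0, 0), "finite")
})

test_that("noiseless on-grid measurements are recovered exactly", {
  p <- tiny_params()
  g <- small_grid()
  set.seed(21)
  picks <- cbind(sample(2:length(g$conc), 5), sample(2:length(g$time), 5))
  tmax <- max(g$time)
  for (k in seq_len(nrow(picks))) {
    c_true <- g$conc[picks[k, 1]]
    t_true <- g$time[picks[k, 2]]
    tc <- simulate_exposure(p, exposure_scenario(c_true, tmax),
                            dt = g$time_step)
    j <- match(round(t_true, 10), round(tc$times, 10))
    est <- estimate_exposure(tc$venous[j], tc$arterial[j], p, g)
    expect_identical(est$conc_hat, c_true)
    expect_equal(est$time_hat, t_true)
    expect_lt(est$sse, 1e-12)
  }
})

test_that("the linear fast path equals the brute-force per-concentration search", {
  p <- tiny_params()
  g <- inversion_grid(conc_min = 0, conc_max = 2000, conc_step = 200,
                      time_min = 0, time_max = 4, time_step = 0.25)
  set.seed(33)
  for (k in 1:20) {
    r <- stats::runif(1, 0.05, 3)
    l <- r * stats::runif(1, 1.05, 4)
    fast <- estimate_exposure(r, l, p, g, method = "linear")
    slow <- estimate_exposure(r, l, p, g, method = "exhaustive")
    expect_identical(fast$conc_hat, slow$conc_hat)
    expect_equal(fast$time_hat, slow$time_hat)
    expect_equal(fast$sse, slow$sse, tolerance = 1e-9)
  }
})

test_that("estimates lie on the grid and survive grid shrinkage", {
  p <- tiny_params()
  g <- small_grid()
  est <- estimate_exposure(0.9, 1.8, p, g)
  expect_true(est$conc_hat %in% g$conc)
  expect_true(any(abs(est$time_hat - g$time) < 1e-9))
  # a window around the optimum returns the same optimum
  win <- inversion_grid(
    conc_min = max(0, est$conc_hat - 3 * g$conc_step),
    conc_max = est$conc_hat + 3 * g$conc_step, conc_step = g$conc_step,
    time_min = max(0, est$time_hat - 3 * g$time_step),
    time_max = min(max(g$time), est$time_hat + 3 * g$time_step),
    time_step = g$time_step)
  est2 <- estimate_exposure(0.9, 1.8, p, win)
  expect_identical(est2$conc_hat, est$conc_hat)
  expect_equal(est2$time_hat, est$time_hat)
})

test_that("the reported sse is reproducible by re-simulating at the optimum", {
  p <- tiny_params()
  g <- small_grid()
  est <- estimate_exposure(0.7, 2.1, p, g)
  tc <- simulate_exposure(p, exposure_scenario(est$conc_hat, max(g$time)),
                          dt = g$time_step)
  j <- match(round(est$time_hat, 10), round(tc$times, 10))
  expect_equal(sse_objective(0.7, 2.1, tc$venous[j], tc$arterial[j]),
               est$sse, tolerance = 1e-9)
})

test_that("degenerate and censored inputs are handled deterministically", {
  p <- tiny_params()
  g <- small_grid()
  # a zero measurement pair ties along the zero-concentration and
  # zero-time edges; the lowest-concentration-then-shortest-time rule
  # settles on the origin
  est <- estimate_exposure(0, 0, p, g)
  expect_identical(est$conc_hat, 0)
  expect_identical(est$time_hat, 0)
  expect_identical(est$n_ties,
                   length(g$conc) + length(g$time) - 1L)
  expect_error(estimate_exposure(NA_real_, 2, p, g), "censored or missing")
  expect_error(estimate_exposure(1, -0.2, p, g), "non-negative")
})

test_that("group classification follows the inclusive/exclusive thresholds", {
  expect_identical(classify_group(14280, 0.05), "Ca_high_T_short")
  expect_identical(classify_group(1032, 8.35), "Ca_low_T_long")
  expect_identical(classify_group(5000, 0.99), "Ca_high_T_short")
  expect_identical(classify_group(5000, 1.00), "Ca_low_T_long")
  expect_identical(classify_group(4999, 0.10), "Ca_low_T_long")
  expect_identical(classify_group(2000, 0.5, conc_threshold = 1500),
                   "Ca_high_T_short")
})

test_that("sensitivity analysis brackets the estimate and nests in delta", {
  p <- tiny_params()
  g <- small_grid()
  base <- estimate_exposure(0.8, 2.0, p, g)
  s0 <- sensitivity_analysis(0.8, 2.0, p, g, delta = 0)
  expect_identical(nrow(s0$table), 1L)
  expect_identical(s0$conc_range, rep(base$conc_hat, 2))
  expect_equal(s0$time_range, rep(base$time_hat, 2))

  s05 <- sensitivity_analysis(0.8, 2.0, p, g, delta = 0.05)
  s15 <- sensitivity_analysis(0.8, 2.0, p, g, delta = 0.15)
  expect_identical(nrow(s15$table), 9L)
  expect_true(s15$conc_range[1] <= s05$conc_range[1])
  expect_true(s15$conc_range[2] >= s05$conc_range[2])
  expect_true(s15$time_range[1] <= s05$time_range[1])
  expect_true(s15$time_range[2] >= s05$time_range[2])
  expect_error(sensitivity_analysis(0.8, 2, p, g, delta = 1), "0, 1")
})

test_that("estimate_cases inverts the eligible cases and lists the rest", {
  p <- tiny_params()
  g <- small_grid()
  tab <- make_case_table(cn_right = c("0.8", "ND", "Trace", "1.2"),
                         cn_left = c("1.9", "0.5", "0.9", "2.5"))
  est <- estimate_cases(tab, p, g)
  expect_identical(nrow(est), 2L)
  expect_identical(est$case_id, c("1", "4"))
  inel <- attr(est, "ineligible")
  expect_identical(inel$case_id, c("2", "3"))
  expect_match(inel$reason[1], "cn_right=ND")
})
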