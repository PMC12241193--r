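test_that("mass-balance derivatives have the right structure and signs", {
  p <- tiny_params()
  nc <- length(p$compartments)

  # quiescent system: no gradients, no fluxes
  d0 <- pbpk_rhs(numeric(nc), p, 0)
  expect_true(all(d0 == 0))

  # clean air in the lungs drives uptake into the arterial pool only
  d1 <- pbpk_rhs(numeric(nc), p, 1)
  expect_gt(d1[[p$arterial]], 0)
  expect_identical(unname(d1[p$tissues]), numeric(length(p$tissues)))
  expect_identical(d1[[p$venous]], 0)
  expect_gt(d1[[".inhaled"]], 0)
  expect_identical(d1[[".exhaled"]], 0)

  expect_error(pbpk_rhs(numeric(nc - 1), p, 1), "compartments")
  expect_error(pbpk_rhs(c(NaN, numeric(nc - 1)), p, 1), "non-finite")
})

test_that("derivatives conserve mass for random states", {
  p <- tiny_params()
  nc <- length(p$compartments)
  set.seed(11)
  for (i in 1:25) {
    state <- stats::runif(nc, 0, 50)
    air <- stats::runif(1, 0, 10)
    d <- pbpk_rhs(state, p, air)
    # oracle: d(body burden)/dt must equal inhaled - exhaled - metabolized
    lhs <- sum(d[p$compartments])
    rhs <- d[[".inhaled"]] - d[[".exhaled"]] - d[[".metabolized"]]
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("simulation of zero exposure is identically zero", {
  tc <- simulate_exposure(tiny_params(), exposure_scenario(0, 5), dt = 0.1)
  expect_true(all(tc$arterial == 0) && all(tc$venous == 0))
  expect_true(all(tc$amounts == 0))
  expect_true(all(tc$inhaled == 0))
})

test_that("output grid is uniform, starts at zero, and is all non-negative", {
  tc <- simulate_exposure(tiny_params(), exposure_scenario(500, 3), dt = 0.05)
  expect_identical(tc$times[1], 0)
  expect_equal(diff(tc$times), rep(0.05, length(tc$times) - 1))
  expect_true(all(tc$amounts >= 0))
  expect_identical(unname(tc$amounts[1, ]),
                   numeric(ncol(tc$amounts)))
  # zero-duration scenario degenerates to the initial condition
  tc0 <- simulate_exposure(tiny_params(), exposure_scenario(500, 0))
  expect_identical(length(tc0$times), 1L)
  expect_identical(tc0$arterial, 0)
})

test_that("the linear model is exactly dose-proportional", {
  p <- tiny_params()
  a <- simulate_exposure(p, exposure_scenario(400, 5), dt = 0.1)
  b <- simulate_exposure(p, exposure_scenario(800, 5), dt = 0.1)
  expect_equal(b$arterial, 2 * a$arterial, tolerance = 1e-9)
  expect_equal(b$venous, 2 * a$venous, tolerance = 1e-9)
  expect_equal(b$metabolized, 2 * a$metabolized, tolerance = 1e-9)
})

test_that("arterial leads venous with a widening gap during early uptake", {
  for (p in list(tiny_params(), default_pbpk_params())) {
    tc <- simulate_exposure(p, exposure_scenario(1000, 10), dt = 0.05)
    expect_true(all(tc$arterial[-1] > tc$venous[-1]))
    gap <- tc$arterial - tc$venous
    early <- tc$times <= 2
    expect_true(all(diff(gap[early]) > 0))
    # rapid initial rise then deceleration: the first-step arterial
    # increment exceeds the increment an output-step later in the run
    inc <- diff(tc$arterial)
    expect_gt(inc[1], inc[length(inc)])
  }
})

test_that("concentrations are non-decreasing in inhaled dose", {
  p <- default_pbpk_params()
  lo <- simulate_exposure(p, exposure_scenario(50, 5), dt = 0.1)
  hi <- simulate_exposure(p, exposure_scenario(250, 5), dt = 0.1)
  expect_true(all(hi$arterial >= lo$arterial))
  expect_true(all(hi$venous >= lo$venous))
})

test_that("mass is conserved along the trajectory", {
  for (p in list(tiny_params(), default_pbpk_params())) {
    tc <- simulate_exposure(p, exposure_scenario(2000, 10), dt = 0.05)
    expect_lt(max(mass_balance_error(tc)), 1e-6)
  }
})

test_that("halving the internal step barely moves the solution", {
  # convergence is measured relative to the solution scale (sup norm):
  # pointwise ratios are ill-conditioned where venous CN rises from zero
  p <- default_pbpk_params()
  c2 <- simulate_exposure(p, exposure_scenario(1000, 10), n_substeps = 2)
  c4 <- simulate_exposure(p, exposure_scenario(1000, 10), n_substeps = 4)
  expect_lt(max(abs(c2$arterial - c4$arterial)) / max(c4$arterial), 1e-6)
  expect_lt(max(abs(c2$venous - c4$venous)) / max(c4$venous), 1e-6)
})

test_that("time-course export writes the tidy schema at full precision", {
  tc <- simulate_exposure(tiny_params(), exposure_scenario(750, 2), dt = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, f)
  expect_identical(readLines(f, n = 1), "# fireCN timecourse v1")
  back <- utils::read.csv(f, comment.char = "#")
  expect_named(back, names(as.data.frame(tc)))
  expect_equal(back$arterial_ug_per_mL, tc$arterial, tolerance = 1e-12)
})
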