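test_that("censored assay tokens parse to the right status", {
  out <- parse_measurement(c("ND", "Trace", "0.48", "-", "", "11"))
  expect_identical(out$status, c("not_detected", "trace", "quantified",
                                 "missing", "missing", "quantified"))
  expect_identical(out$value, c(NA, NA, 0.48, NA, NA, 11))
  expect_error(parse_measurement("abc"), "unrecognized")
  expect_error(parse_measurement("abc", what = "cn_right"), "cn_right")
  # a numeric below the LOQ has no business being quantified
  expect_error(parse_measurement("0.3"), "below LOQ")
  expect_error(parse_measurement("1.0", lod = 0.5, loq = 0.4), "below")
})

test_that("case-table CSV round-trips statuses and values exactly", {
  cases <- fire_cohort()
  f <- withr::local_tempfile(fileext = ".csv")
  write_case_table(cases, f)
  back <- read_case_table(f)
  for (col in c("case_id", "cn_right_status", "cn_left_status",
                "cn_right", "cn_left", "cohb_right", "cohb_left",
                "scn_right", "scn_left")) {
    expect_identical(back[[col]], cases[[col]], info = col)
  }
})

test_that("detection counts a case when either chamber is at least trace", {
  all_nd <- make_case_table(cn_right = rep("ND", 4), cn_left = rep("ND", 4))
  d <- detection_summary(all_nd)
  expect_identical(d$n_detected, 0L)
  expect_identical(d$percent, 0)

  one_trace <- make_case_table(cn_right = c("ND", "ND"),
                               cn_left = c("Trace", "ND"))
  expect_identical(detection_summary(one_trace)$n_detected, 1L)

  # invariant to row order
  cases <- fire_cohort()
  shuffled <- cases[rev(seq_len(nrow(cases))), ]
  expect_identical(detection_summary(shuffled)$percent,
                   detection_summary(cases)$percent)
  expect_error(detection_summary(cases[0, ]), "empty")
})

test_that("zone classification partitions the (COHb, CN) plane", {
  # quantified CN >= 1 with COHb < 50: HCN-dominant
  expect_identical(zone_classify(13, "quantified", 1.7), 2L)
  # censored CN counts below the threshold
  expect_identical(zone_classify(9.2, "not_detected", NA), 1L)
  expect_identical(zone_classify(57, "trace", NA), 3L)
  expect_identical(zone_classify(79, "quantified", 2.0), 4L)
  # every classifiable case falls in exactly one zone; counts add up
  cases <- fire_cohort()
  z <- zone_classify(cases$cohb_right, cases$cn_right_status,
                     cases$cn_right)
  expect_true(all(z %in% 1:4))
  expect_identical(sum(table(z)), nrow(cases))
  expect_error(zone_classify(NA, "quantified", 2), "COHb")
  expect_error(zone_classify(50, "missing", NA), "required")
})

test_that("left-right dominance handles ties and empty eligible sets", {
  tab <- make_case_table(cn_right = c("1.0", "2.0", "ND"),
                         cn_left = c("1.0", "3.0", "1.5"))
  d <- left_right_dominance(tab)
  expect_identical(d$n_eligible, 2L)
  expect_identical(d$n_ties, 1L)
  expect_identical(d$n_left_higher, 1L)
  expect_identical(d$excluded_ids, "3")

  none <- make_case_table(cn_right = c("ND", "Trace"),
                          cn_left = c("ND", "ND"))
  expect_warning(d0 <- left_right_dominance(none), "undefined")
  expect_true(is.na(d0$proportion))
})

test_that("the pooled t-test agrees with the textbook closed form", {
  x <- c(1.0, 2.0, 4.0)
  y <- c(2.5, 3.5, 6.0)
  res <- scn_group_comparison(x, y, method = "pooled")
  # independent closed-form oracle
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  df_hand <- length(x) + length(y) - 2
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, p_hand, tolerance = 1e-12)

  same <- scn_group_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  paired <- scn_group_comparison(c(2, 3, 5), c(1, 2, 3), method = "paired")
  expect_equal(paired$df, 2)
  expect_error(scn_group_comparison(1, 2), ">= 2")
  # missing values are excluded pairwise for the paired variant
  pw <- scn_group_comparison(c(2, 3.5, 4, NA), c(1, 2, NA, 5),
                             method = "paired")
  expect_equal(pw$df, 1)
})

test_that("the cohort report assembles counts, flags and group tests", {
  cases <- fire_cohort()
  rep <- cohort_report(cases, estimates = exposure_groups_reference())
  expect_identical(rep$detection$n_detected, 23L)
  expect_identical(unname(rep$zone_counts["zone2"]), 3L)
  expect_identical(sum(rep$zone_counts), nrow(cases))
  expect_equal(rep$scn_range, c(0.92, 8.5))
  expect_identical(rep$cohb_flags, character(0))
  expect_lt(rep$scn_tests[["Ca_high_T_short"]]$p, 0.01)
  expect_gt(rep$scn_tests[["Ca_low_T_long"]]$p, 0.05)
  expect_output(print(rep), "23 of 29")

  # implausibly low COHb is flagged
  low <- make_case_table(cn_right = c("1.0", "ND"),
                         cn_left = c("2.0", "ND"),
                         cohb_right = c("1.5", "60"))
  expect_identical(cohort_report(low)$cohb_flags, "1")

  empty <- cohort_report(fire_cohort()[0, ])
  expect_identical(empty$n_cases, 0L)
  expect_match(empty$warnings, "empty")
  expect_output(print(empty), "empty cohort")
})
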