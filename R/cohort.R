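#' Parse a censored cyanide assay token
#'
#' The CN assay reports `"ND"` (not detected, below the limit of
#' detection), `"Trace"` (detected but below the lower limit of
#' quantification), a non-negative decimal (quantified), or a missing
#' marker (`"-"`, en dash, or empty) when no sample was available.
#'
#' @param token character vector of assay tokens.
#' @param lod limit of detection, ug/mL (default 0.2).
#' @param loq lower limit of quantification, ug/mL (default 0.4); must
#'   exceed `lod`.
#' @param what label used in error messages to locate a bad token.
#' @return a data frame with columns `status` (one of `not_detected`,
#'   `trace`, `quantified`, `missing`) and `value` (numeric, `NA` unless
#'   quantified).
#' @examples
#' parse_measurement(c("ND", "Trace", "0.48", "-"))
#' @export
parse_measurement <- function(token, lod = 0.2, loq = 0.4, what = "token") {
  if (lod >= loq) stop("'lod' must be below 'loq'")
  token <- trimws(as.character(token))
  status <- character(length(token))
  value <- rep(NA_real_, length(token))
  for (i in seq_along(token)) {
    tk <- token[i]
    if (is.na(tk) || tk %in% c("", "-", "–")) {
      status[i] <- "missing"
    } else if (toupper(tk) == "ND") {
      status[i] <- "not_detected"
    } else if (tolower(tk) == "trace") {
      status[i] <- "trace"
    } else {
      v <- suppressWarnings(as.numeric(tk))
      if (is.na(v) || v < 0) {
        stop(sprintf("unrecognized measurement token '%s' (%s, entry %d)",
                     tk, what, i))
      }
      if (v < loq) {
        stop(sprintf(
          "quantified value %g below LOQ %g (%s, entry %d); encode as 'Trace' or 'ND'",
          v, loq, what, i))
      }
      status[i] <- "quantified"
      value[i] <- v
    }
  }
  data.frame(status = status, value = value)
}

#' Read a fire-death case table
#'
#' CSV schema (header required, `#` comment lines ignored): `case_id`,
#' `age`, `sex`, `cn_right`, `cn_left`, `cohb_right`, `cohb_left`,
#' `scn_right`, `scn_left`. CN columns hold assay tokens (decimal, `ND`,
#' `Trace`); SCN and COHb columns hold decimals or the missing marker.
#'
#' @param path CSV file path.
#' @param lod,loq CN assay censoring limits, ug/mL.
#' @return a `cn_case_table` data frame: the original CN tokens are kept
#'   in `cn_right_token`/`cn_left_token`, parsed status in
#'   `cn_right_status`/`cn_left_status`, and numeric values (NA when
#'   censored) in `cn_right`/`cn_left`. `lod` and `loq` are attached as
#'   attributes.
#' @export
read_case_table <- function(path, lod = 0.2, loq = 0.4) {
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         strip.white = TRUE)
  needed <- c("case_id", "age", "sex", "cn_right", "cn_left",
              "cohb_right", "cohb_left", "scn_right", "scn_left")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("case table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  as_case_table(raw, lod = lod, loq = loq)
}

# Assemble a cn_case_table from raw character columns.
as_case_table <- function(raw, lod = 0.2, loq = 0.4) {
  pr <- parse_measurement(raw$cn_right, lod, loq, what = "cn_right")
  pl <- parse_measurement(raw$cn_left, lod, loq, what = "cn_left")
  num <- function(x) suppressWarnings(as.numeric(ifelse(
    trimws(x) %in% c("", "-", "–"), NA, x)))
  out <- data.frame(
    case_id = raw$case_id,
    age = num(raw$age),
    sex = raw$sex,
    cn_right_token = raw$cn_right, cn_left_token = raw$cn_left,
    cn_right_status = pr$status, cn_left_status = pl$status,
    cn_right = pr$value, cn_left = pl$value,
    cohb_right = num(raw$cohb_right), cohb_left = num(raw$cohb_left),
    scn_right = num(raw$scn_right), scn_left = num(raw$scn_left)
  )
  bad_cohb <- !is.na(out$cohb_right) & (out$cohb_right < 0 | out$cohb_right > 100) |
    !is.na(out$cohb_left) & (out$cohb_left < 0 | out$cohb_left > 100)
  if (any(bad_cohb)) {
    stop("COHb% outside [0, 100] for case(s): ",
         paste(out$case_id[bad_cohb], collapse = ", "))
  }
  attr(out, "lod") <- lod
  attr(out, "loq") <- loq
  class(out) <- c("cn_case_table", "data.frame")
  out
}

#' Write a case table in the interchange CSV schema
#'
#' Inverse of [read_case_table()]: censoring statuses are re-encoded as
#' their tokens, quantified values at full precision, so a write/read
#' round trip preserves every status and value exactly.
#'
#' @param cases a `cn_case_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_case_table <- function(cases, path) {
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE,
                                                 scientific = FALSE))
  out <- data.frame(
    case_id = cases$case_id, age = fmt(cases$age), sex = cases$sex,
    cn_right = cases$cn_right_token, cn_left = cases$cn_left_token,
    cohb_right = fmt(cases$cohb_right), cohb_left = fmt(cases$cohb_left),
    scn_right = fmt(cases$scn_right), scn_left = fmt(cases$scn_left)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fireCN case-table v1", con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Packaged fire-death cohort
#'
#' The packaged table of 29 fire-related autopsy cases: age, sex, cyanide
#' concentration in right and left cardiac blood (censored at LOD 0.2 /
#' LOQ 0.4 ug/mL), carboxyhemoglobin percentage and thiocyanate
#' concentration in both chambers.
#'
#' @return a `cn_case_table` (see [read_case_table()]).
#' @export
fire_cohort <- function() {
  read_case_table(system.file("extdata", "fire_deaths_cohort.csv",
                              package = "fireCN", mustWork = TRUE))
}

#' Reference exposure groups for the packaged cohort
#'
#' The 13 doubly-quantified cases of the packaged cohort with their
#' thiocyanate values, reference exposure estimates and exposure-group
#' assignment (`Ca_high_T_short` / `Ca_low_T_long`) as reported alongside
#' the cohort. Used for the group-wise SCN comparison.
#'
#' @return a data frame with `case_id`, `cn_right`, `cn_left`,
#'   `scn_right`, `scn_left`, `ref_conc_ppm`, `ref_time_min`, `group`.
#' @export
exposure_groups_reference <- function() {
  utils::read.csv(system.file("extdata", "fire_deaths_groups.csv",
                              package = "fireCN", mustWork = TRUE),
                  comment.char = "#")
}

# round-half-up to `digits` decimals (base round() is round-half-even,
# which would report 0.05-resolution percentages inconsistently)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Cohort detection summary
#'
#' A case counts as CN-detected when either cardiac chamber is at least at
#' the limit of detection, i.e. its status is `trace` or `quantified`.
#'
#' @param cases a `cn_case_table`.
#' @return list with `n_detected`, `n_total`, `percent` (one decimal,
#'   half-up) and the detected case ids.
#' @export
detection_summary <- function(cases) {
  if (nrow(cases) == 0) stop("empty case table")
  det <- cases$cn_right_status %in% c("trace", "quantified") |
    cases$cn_left_status %in% c("trace", "quantified")
  list(n_detected = sum(det), n_total = nrow(cases),
       percent = round_half_up(100 * sum(det) / nrow(cases), 1),
       detected_ids = cases$case_id[det])
}

#' Poisoning-zone classification
#'
#' Quadrants of the (COHb%, CN) plane at the conventional poisoning
#' thresholds, evaluated on right cardiac blood as the venous proxy:
#' zone 1 = both below threshold (sub-lethal), zone 2 = CN at/above 1
#' ug/mL with COHb below 50% (HCN-dominant), zone 3 = COHb at/above 50%
#' with CN below (CO-dominant), zone 4 = both at/above threshold.
#' Censored CN (`ND`/`Trace`) counts as below the CN threshold.
#'
#' @param cohb COHb percentage (venous proxy chamber).
#' @param cn_status CN censoring status vector (as in a `cn_case_table`).
#' @param cn_value quantified CN value, ug/mL (`NA` when censored).
#' @param cohb_threshold,cn_threshold thresholds; defaults 50% and 1 ug/mL.
#' @return integer vector of zones 1-4.
#' @export
zone_classify <- function(cohb, cn_status, cn_value,
                          cohb_threshold = 50, cn_threshold = 1) {
  if (any(is.na(cohb))) stop("COHb% is required for zone classification")
  if (any(cn_status == "missing")) {
    stop("a CN measurement (censored allowed) is required for zone classification")
  }
  cn_high <- cn_status == "quantified" & !is.na(cn_value) &
    cn_value >= cn_threshold
  co_high <- cohb >= cohb_threshold
  1L + 1L * cn_high + 2L * co_high
}

#' Left-vs-right cardiac CN dominance
#'
#' Among the cases with quantified CN in both chambers, the proportion in
#' which left cardiac blood exceeds right cardiac blood - the hallmark of
#' inhaled HCN gas (arterial blood leads venous during uptake). Cases with
#' any censored CN cannot be ordered and are reported separately.
#'
#' @param cases a `cn_case_table`.
#' @return list with `n_left_higher`, `n_ties`, `n_eligible`,
#'   `proportion` (`NA` with a warning when no case is eligible),
#'   `eligible_ids`, `excluded_ids`.
#' @export
left_right_dominance <- function(cases) {
  elig <- cases$cn_right_status == "quantified" &
    cases$cn_left_status == "quantified"
  n <- sum(elig)
  if (n == 0) {
    warning("no case with quantified CN in both chambers; proportion undefined")
    return(list(n_left_higher = 0L, n_ties = 0L, n_eligible = 0L,
                proportion = NA_real_, eligible_ids = character(0),
                excluded_ids = cases$case_id[!elig]))
  }
  l <- cases$cn_left[elig]; r <- cases$cn_right[elig]
  list(n_left_higher = sum(l > r), n_ties = sum(l == r), n_eligible = n,
       proportion = sum(l > r) / n,
       eligible_ids = cases$case_id[elig],
       excluded_ids = cases$case_id[!elig])
}

#' Right-vs-left thiocyanate comparison within an exposure group
#'
#' Two-sided t-test comparing SCN concentration in right versus left
#' cardiac blood. The default is the unpaired pooled-variance Student
#' test; Welch and paired variants are available. Missing SCN values are
#' dropped (pairwise for the paired test).
#'
#' @param scn_right,scn_left SCN concentrations, ug/mL.
#' @param method `"pooled"` (default), `"welch"` or `"paired"`.
#' @return list with `t`, `df`, `p`, `mean_right`, `mean_left`, `method`.
#' @export
scn_group_comparison <- function(scn_right, scn_left,
                                 method = c("pooled", "welch", "paired")) {
  method <- match.arg(method)
  if (method == "paired") {
    ok <- !is.na(scn_right) & !is.na(scn_left)
    scn_right <- scn_right[ok]; scn_left <- scn_left[ok]
    if (sum(ok) < 2) stop("paired SCN comparison needs >= 2 complete pairs")
    ht <- stats::t.test(scn_right, scn_left, paired = TRUE)
  } else {
    scn_right <- scn_right[!is.na(scn_right)]
    scn_left <- scn_left[!is.na(scn_left)]
    if (length(scn_right) < 2 || length(scn_left) < 2) {
      stop("SCN comparison needs >= 2 values per chamber")
    }
    ht <- stats::t.test(scn_right, scn_left,
                        var.equal = (method == "pooled"))
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       mean_right = mean(scn_right), mean_left = mean(scn_left),
       method = method)
}

#' Assembled forensic cohort report
#'
#' One structured summary of a case table: detection summary, poisoning
#' zone counts (right cardiac blood as venous proxy), left-right CN
#' dominance, SCN concentration range, COHb plausibility flags (any case
#' at or below 2.0% COHb - the upper bound in healthy non-smokers - is
#' inconsistent with fire-gas exposure), and, when exposure-group labels
#' are supplied, the per-group right-vs-left SCN comparison.
#'
#' @param cases a `cn_case_table`.
#' @param estimates optional data frame with `case_id` and `group`
#'   (e.g. from [estimate_cases()] or [exposure_groups_reference()]).
#' @param cohb_floor flag threshold for implausibly low COHb, percent.
#' @param ttest_method passed to [scn_group_comparison()].
#' @return a `cohort_report` list; see the print method for the layout.
#' @export
cohort_report <- function(cases, estimates = NULL, cohb_floor = 2.0,
                          ttest_method = "pooled") {
  warnings <- character(0)
  if (nrow(cases) == 0) {
    warnings <- "empty cohort: nothing to report"
    rep <- list(n_cases = 0L, detection = NULL, zone_counts = NULL,
                dominance = NULL, scn_range = NULL, cohb_flags = character(0),
                scn_tests = NULL, warnings = warnings)
    class(rep) <- "cohort_report"
    return(rep)
  }
  det <- detection_summary(cases)
  classifiable <- !is.na(cases$cohb_right) & cases$cn_right_status != "missing"
  zones <- zone_classify(cases$cohb_right[classifiable],
                         cases$cn_right_status[classifiable],
                         cases$cn_right[classifiable])
  zone_counts <- stats::setNames(
    vapply(1:4, function(z) sum(zones == z), 0L),
    paste0("zone", 1:4))
  dom <- withCallingHandlers(
    left_right_dominance(cases),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  scn_all <- c(cases$scn_right, cases$scn_left)
  scn_range <- if (all(is.na(scn_all))) NULL else range(scn_all, na.rm = TRUE)
  low_cohb <- !is.na(cases$cohb_right) & cases$cohb_right <= cohb_floor |
    !is.na(cases$cohb_left) & cases$cohb_left <= cohb_floor
  cohb_flags <- cases$case_id[low_cohb]

  scn_tests <- NULL
  if (!is.null(estimates) && nrow(estimates) > 0) {
    merged <- merge(cases, estimates[, c("case_id", "group")], by = "case_id")
    scn_tests <- lapply(split(merged, merged$group), function(g) {
      res <- try(scn_group_comparison(g$scn_right, g$scn_left,
                                      method = ttest_method), silent = TRUE)
      if (inherits(res, "try-error")) {
        warnings <<- c(warnings, paste("SCN test skipped for group",
                                       g$group[1], "- insufficient data"))
        NULL
      } else res
    })
  }
  rep <- list(n_cases = nrow(cases), detection = det,
              zone_counts = zone_counts, n_classifiable = sum(classifiable),
              dominance = dom, scn_range = scn_range,
              cohb_flags = cohb_flags, cohb_floor = cohb_floor,
              scn_tests = scn_tests, warnings = warnings)
  class(rep) <- "cohort_report"
  rep
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Forensic cohort report\n")
  cat("----------------------\n")
  if (x$n_cases == 0) {
    cat("  (empty cohort)\n")
    for (w in x$warnings) cat("  warning:", w, "\n")
    return(invisible(x))
  }
  cat(sprintf("  cases: %d\n", x$n_cases))
  cat(sprintf("  CN detected (either chamber): %d of %d (%.1f%%)\n",
              x$detection$n_detected, x$detection$n_total,
              x$detection$percent))
  cat(sprintf("  poisoning zones (right cardiac blood, %d classifiable): %s\n",
              x$n_classifiable,
              paste(sprintf("%s=%d", names(x$zone_counts), x$zone_counts),
                    collapse = ", ")))
  if (!is.na(x$dominance$proportion)) {
    cat(sprintf("  left > right CN: %d of %d doubly-quantified cases (%.1f%%)\n",
                x$dominance$n_left_higher, x$dominance$n_eligible,
                100 * x$dominance$proportion))
  }
  if (!is.null(x$scn_range)) {
    cat(sprintf("  SCN range: %.3g-%.3g ug/mL\n",
                x$scn_range[1], x$scn_range[2]))
  }
  if (length(x$cohb_flags)) {
    cat(sprintf("  COHb <= %.1f%% (inconsistent with fire exposure): %s\n",
                x$cohb_floor, paste(x$cohb_flags, collapse = ", ")))
  } else {
    cat(sprintf("  all cases exceed %.1f%% COHb\n", x$cohb_floor))
  }
  if (!is.null(x$scn_tests)) {
    for (g in names(x$scn_tests)) {
      tst <- x$scn_tests[[g]]
      if (is.null(tst)) next
      cat(sprintf(
        "  SCN right vs left, %s: mean %.3g vs %.3g, t = %.3f (df %.3g), p = %.4f [%s]\n",
        g, tst$mean_right, tst$mean_left, tst$t, tst$df, tst$p, tst$method))
    }
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Machine-readable summary of a cohort report
#'
#' Flattens a [cohort_report()] into plain lists/vectors suitable for JSON
#' serialisation.
#'
#' @param report a `cohort_report`.
#' @return a named list of scalars and simple vectors.
#' @export
report_as_list <- function(report) {
  out <- list(n_cases = report$n_cases)
  if (report$n_cases > 0) {
    out$detection <- report$detection[c("n_detected", "n_total", "percent")]
    out$zone_counts <- as.list(report$zone_counts)
    out$dominance <- report$dominance[c("n_left_higher", "n_ties",
                                        "n_eligible", "proportion")]
    out$scn_range <- report$scn_range
    out$cohb_flags <- report$cohb_flags
    if (!is.null(report$scn_tests)) {
      out$scn_tests <- lapply(report$scn_tests, function(t)
        if (is.null(t)) NULL else t[c("t", "df", "p", "method")])
    }
  }
  out$warnings <- report$warnings
  out
}
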