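#' Pipeline entry points
#'
#' Thin, configuration-driven wrappers tying the modules together; each
#' returns its result invisibly and optionally writes the standard CSV /
#' JSON artefacts. They are also the backend of the command-line script
#' shipped at `inst/cli/firecn.R` (run `Rscript
#' $(Rscript -e 'cat(system.file("cli/firecn.R", package="fireCN"))') --help`).
#' All numeric CSV output is written at full precision; rounding happens
#' only in the printed report layer.
#'
#' @param params a `pbpk_params` object, or a path to a YAML parameter
#'   file, or `NULL` for [default_pbpk_params()].
#' @param ppm,duration,dt forward-simulation scenario settings.
#' @param out optional output path; when `NULL` nothing is written.
#' @return `run_simulate`: the `cn_timecourse`, invisibly.
#' @name pipeline
NULL

resolve_params <- function(params) {
  if (is.null(params)) return(default_pbpk_params())
  if (inherits(params, "pbpk_params")) return(params)
  if (is.character(params) && length(params) == 1) {
    return(read_pbpk_params(params))
  }
  stop("'params' must be a pbpk_params object, a YAML path, or NULL")
}

resolve_cases <- function(cases) {
  if (inherits(cases, "cn_case_table")) return(cases)
  if (is.character(cases) && length(cases) == 1) return(read_case_table(cases))
  stop("'cases' must be a cn_case_table or a CSV path")
}

#' @rdname pipeline
#' @export
run_simulate <- function(ppm, duration, params = NULL, dt = 0.05,
                         out = NULL) {
  p <- resolve_params(params)
  tc <- simulate_exposure(p, exposure_scenario(ppm, duration), dt = dt)
  if (!is.null(out)) write_timecourse(tc, out)
  invisible(tc)
}

#' @rdname pipeline
#' @param cases a `cn_case_table` or a case-table CSV path.
#' @param grid an [inversion_grid()].
#' @param conc_threshold,time_threshold grouping thresholds.
#' @return `run_estimate`: the estimates data frame (see
#'   [estimate_cases()]), invisibly.
#' @export
run_estimate <- function(cases, params = NULL, grid = inversion_grid(),
                         conc_threshold = 5000, time_threshold = 1,
                         out = NULL) {
  tab <- resolve_cases(cases)
  est <- estimate_cases(tab, resolve_params(params), grid,
                        conc_threshold = conc_threshold,
                        time_threshold = time_threshold)
  if (!is.null(out)) {
    con <- file(out, "w")
    on.exit(close(con))
    writeLines("# fireCN estimates v1", con)
    utils::write.csv(est, con, row.names = FALSE)
  }
  invisible(est)
}

#' @rdname pipeline
#' @param estimates optional estimates table (with `case_id`, `group`)
#'   for the group-wise SCN comparison.
#' @param ttest_method passed to [scn_group_comparison()].
#' @return `run_cohort`: the `cohort_report`, invisibly.
#' @export
run_cohort <- function(cases, estimates = NULL, ttest_method = "pooled",
                       out = NULL) {
  tab <- resolve_cases(cases)
  rep <- cohort_report(tab, estimates = estimates,
                       ttest_method = ttest_method)
  print(rep)
  if (!is.null(out)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("writing a JSON report requires the 'jsonlite' package")
    }
    jsonlite::write_json(report_as_list(rep), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(rep)
}

#' @rdname pipeline
#' @param spec a [synthetic_spec()].
#' @param out_truth optional path for the hidden-truth CSV.
#' @return `run_synth`: the `list(cases, truth)` from [generate_cases()],
#'   invisibly.
#' @export
run_synth <- function(spec, params = NULL, out = NULL, out_truth = NULL) {
  g <- generate_cases(spec, resolve_params(params))
  if (!is.null(out)) write_case_table(g$cases, out)
  if (!is.null(out_truth)) {
    con <- file(out_truth, "w")
    on.exit(close(con))
    writeLines("# fireCN truth-table v1", con)
    utils::write.csv(g$truth, con, row.names = FALSE)
  }
  invisible(g)
}

#' @rdname pipeline
#' @param cn_right,cn_left quantified CN measurements, ug/mL.
#' @param delta relative perturbation of the sensitivity analysis.
#' @param case_id identifier carried through.
#' @return `run_sensitivity`: the `sensitivity_result`, invisibly.
#' @export
run_sensitivity <- function(cn_right, cn_left, params = NULL,
                            grid = inversion_grid(), delta = 0.15,
                            case_id = NULL, out = NULL) {
  sens <- sensitivity_analysis(cn_right, cn_left, resolve_params(params),
                               grid, delta = delta, case_id = case_id)
  print(sens)
  if (!is.null(out)) {
    con <- file(out, "w")
    on.exit(close(con))
    writeLines("# fireCN sensitivity v1", con)
    utils::write.csv(sens$table, con, row.names = FALSE)
  }
  invisible(sens)
}
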