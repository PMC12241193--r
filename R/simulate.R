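#' Constant-concentration HCN inhalation scenario
#'
#' @param ppm inhaled HCN concentration in inspired air, ppm (v/v); >= 0.
#' @param duration inhalation time, minutes; >= 0. The simulation stops at
#'   the end of inhalation (the forensic endpoint is death at the end of
#'   exposure); no post-exposure phase is modelled.
#' @param temperature_celsius optional reference temperature for the
#'   ppm-to-mass conversion; `NULL` uses the molar volume stored in the
#'   parameter set.
#' @return an `exposure_scenario` object.
#' @export
exposure_scenario <- function(ppm, duration, temperature_celsius = NULL) {
  stopifnot(is.numeric(ppm), length(ppm) == 1, is.finite(ppm),
            is.numeric(duration), length(duration) == 1, is.finite(duration))
  if (ppm < 0) stop("'ppm' must be non-negative")
  if (duration < 0) stop("'duration' must be non-negative")
  structure(list(ppm = ppm, duration = duration,
                 temperature_celsius = temperature_celsius),
            class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("HCN exposure scenario: %.6g ppm for %.6g min\n",
              x$ppm, x$duration))
  invisible(x)
}

# State layout used by the integrator: one amount (mg) per compartment in
# params$compartments order, followed by the three bookkeeping integrals
# (metabolized, exhaled, inhaled; mg). Blood concentration in mg/L is
# numerically identical to ug/mL.
state_names <- function(params) {
  c(params$compartments, ".metabolized", ".exhaled", ".inhaled")
}

#' Right-hand side of the PBPK mass balance
#'
#' Flow-limited mass balance over compartment amounts (micrograms are used
#' at the user interface; internally milligrams — the derivative is linear
#' so the unit cancels). Pulmonary uptake into the gas-exchange/arterial
#' compartment is `alveolar_ventilation * (C_air - C_art /
#' blood_air_partition)`, split for bookkeeping into a gross inhaled term
#' and a gross exhaled term. Each tissue exchanges at `flow * (C_art -
#' C_tissue / partition)`; the venous pool collects the flow-weighted
#' tissue effluents and returns to the arterial pool at cardiac output.
#' First-order elimination `k_met * amount` applies per compartment. The
#' derivative of (body burden + metabolized + exhaled - inhaled) is
#' identically zero, which makes mass conservation checkable to solver
#' precision.
#'
#' @param state named or unnamed numeric vector of compartment amounts, in
#'   `params$compartments` order. May optionally carry the three
#'   bookkeeping entries; they do not feed back into the dynamics.
#' @param params a `pbpk_params` object.
#' @param air_concentration HCN mass concentration in inspired air, mg/L.
#' @return numeric vector of time derivatives (amount/min) for the full
#'   state including the bookkeeping integrals, named.
#' @export
pbpk_rhs <- function(state, params, air_concentration) {
  nc <- length(params$compartments)
  if (length(state) == nc + 3) state <- state[seq_len(nc)]
  if (length(state) != nc) {
    stop(sprintf("state has length %d but the model has %d compartments",
                 length(state), nc))
  }
  if (any(!is.finite(state)) || !is.finite(air_concentration)) {
    stop("non-finite value in state or air concentration")
  }
  a <- stats::setNames(as.numeric(state), params$compartments)
  conc <- a / params$volumes[params$compartments]
  c_art <- conc[[params$arterial]]
  c_ven <- conc[[params$venous]]

  inhaled <- params$alveolar_ventilation * air_concentration
  exhaled <- params$alveolar_ventilation * c_art / params$blood_air_partition
  met <- params$k_met * a

  d <- stats::setNames(numeric(nc), params$compartments)
  tiss <- params$tissues
  venous_eff <- params$flows[tiss] * conc[tiss] / params$partitions[tiss]
  d[tiss] <- params$flows[tiss] * (c_art - conc[tiss] / params$partitions[tiss]) -
    met[tiss]
  d[[params$arterial]] <- inhaled - exhaled +
    params$cardiac_output * (c_ven - c_art) - met[[params$arterial]]
  d[[params$venous]] <- sum(venous_eff) - params$cardiac_output * c_ven -
    met[[params$venous]]

  c(d, .metabolized = sum(met), .exhaled = exhaled, .inhaled = inhaled)
}

#' Simulate blood cyanide during HCN gas inhalation
#'
#' Integrates the flow-limited PBPK mass balance with the classic
#' fixed-step fourth-order Runge-Kutta scheme (via
#' [deSolve::ode()] with `method = "rk4"`), reporting arterial and venous
#' blood CN concentration on a uniform output grid. The inhaled air
#' concentration is constant over the whole window. State variables are
#' amounts, so the mass-balance closure (inhaled = body burden +
#' metabolized + exhaled) holds to solver precision at every output time.
#'
#' @param params a `pbpk_params` object.
#' @param scenario an `exposure_scenario` (or a list with `ppm` and
#'   `duration`).
#' @param dt output time step, min (default 0.05).
#' @param n_substeps number of internal RK4 steps per output interval
#'   (default 1). Increase to check step-size convergence.
#' @return a `cn_timecourse` object: list with `times` (min), `arterial`
#'   and `venous` (ug/mL), `amounts` (time x compartment matrix, ug),
#'   `metabolized`, `exhaled`, `inhaled` (cumulative ug), plus the inputs.
#' @examples
#' tc <- simulate_exposure(default_pbpk_params(), exposure_scenario(1000, 5))
#' head(as.data.frame(tc))
#' @export
simulate_exposure <- function(params, scenario, dt = 0.05, n_substeps = 1L) {
  validate_pbpk_params(params)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a single positive number")
  }
  n_substeps <- as.integer(n_substeps)
  if (is.na(n_substeps) || n_substeps < 1) stop("'n_substeps' must be >= 1")
  if (is.numeric(scenario)) stop("'scenario' must be an exposure_scenario")
  ppm <- scenario$ppm
  duration <- scenario$duration
  if (is.null(ppm) || is.null(duration)) {
    stop("'scenario' must provide 'ppm' and 'duration'")
  }

  nc <- length(params$compartments)
  nm <- state_names(params)

  t_out <- seq(0, duration, by = dt)
  if (t_out[length(t_out)] < duration) t_out <- c(t_out, duration)

  if (length(t_out) == 1L) {
    # zero-duration exposure: the initial condition is the whole answer
    amounts <- matrix(0, 1, nc, dimnames = list(NULL, params$compartments))
    return(new_cn_timecourse(0, 0, 0, amounts, 0, 0, 0, params, scenario, dt))
  }

  c_air <- ppm_to_air_concentration(ppm, params, scenario$temperature_celsius)

  t_fine <- t_out
  if (n_substeps > 1L) {
    steps <- diff(t_out)
    t_fine <- c(0, unlist(lapply(seq_along(steps), function(i) {
      t_out[i] + steps[i] * seq_len(n_substeps) / n_substeps
    })))
  }

  deriv <- function(t, y, parms) {
    list(unname(pbpk_rhs(y, params, c_air)))
  }
  y0 <- stats::setNames(numeric(nc + 3), nm)
  sol <- deSolve::ode(y = y0, times = t_fine, func = deriv, parms = NULL,
                      method = "rk4")
  if (any(!is.finite(sol))) {
    bad <- which(rowSums(!is.finite(sol)) > 0)[1]
    stop(sprintf("integration produced non-finite values near t = %.4g min",
                 sol[bad, 1]))
  }
  keep <- match(round(t_out, 10), round(sol[, 1], 10))
  sol <- sol[keep, , drop = FALSE]

  amounts_mg <- sol[, params$compartments, drop = FALSE]
  art <- amounts_mg[, params$arterial] / params$volumes[[params$arterial]]
  ven <- amounts_mg[, params$venous] / params$volumes[[params$venous]]

  new_cn_timecourse(
    times = sol[, 1],
    arterial = unname(art),
    venous = unname(ven),
    amounts = amounts_mg * 1000,
    metabolized = unname(sol[, ".metabolized"]) * 1000,
    exhaled = unname(sol[, ".exhaled"]) * 1000,
    inhaled = unname(sol[, ".inhaled"]) * 1000,
    params = params, scenario = scenario, dt = dt
  )
}

new_cn_timecourse <- function(times, arterial, venous, amounts, metabolized,
                              exhaled, inhaled, params, scenario, dt) {
  structure(
    list(times = times, arterial = arterial, venous = venous,
         amounts = amounts, metabolized = metabolized, exhaled = exhaled,
         inhaled = inhaled, params = params, scenario = scenario, dt = dt),
    class = "cn_timecourse"
  )
}

#' @export
print.cn_timecourse <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "CN time course: %.6g ppm for %.6g min (%d points, dt = %g min)\n",
    x$scenario$ppm, x$scenario$duration, n, x$dt))
  cat(sprintf("  final arterial %.4g ug/mL, venous %.4g ug/mL\n",
              x$arterial[n], x$venous[n]))
  invisible(x)
}

#' @export
as.data.frame.cn_timecourse <- function(x, ...) {
  amt <- x$amounts
  colnames(amt) <- paste0("amount_", colnames(amt), "_ug")
  data.frame(
    time_min = x$times,
    arterial_ug_per_mL = x$arterial,
    venous_ug_per_mL = x$venous,
    amt,
    metabolized_ug = x$metabolized,
    exhaled_ug = x$exhaled,
    inhaled_ug = x$inhaled,
    check.names = FALSE
  )
}

#' Export a simulated time course as tidy CSV
#'
#' Columns: `time_min`, `arterial_ug_per_mL`, `venous_ug_per_mL`, one
#' `amount_<compartment>_ug` column per compartment, and the cumulative
#' `metabolized_ug`, `exhaled_ug`, `inhaled_ug` integrals. Full precision;
#' a schema comment line heads the file.
#'
#' @param tc a `cn_timecourse`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "cn_timecourse"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fireCN timecourse v1", con)
  utils::write.csv(as.data.frame(tc), con, row.names = FALSE)
  invisible(path)
}

#' Mass-balance residual of a simulated time course
#'
#' Relative closure error `|inhaled - (burden + metabolized + exhaled)| /
#' max(inhaled)` at every output time; should be at solver precision
#' (well below 1e-6) for any admissible parameter set.
#'
#' @param tc a `cn_timecourse`.
#' @return numeric vector, one value per output time.
#' @export
mass_balance_error <- function(tc) {
  burden <- rowSums(tc$amounts)
  scale <- max(tc$inhaled, 1e-12)
  abs(tc$inhaled - (burden + tc$metabolized + tc$exhaled)) / scale
}
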