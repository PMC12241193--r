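#' PBPK parameter set for HCN inhalation
#'
#' Constructs and validates the parameter set of the flow-limited,
#' multi-compartment inhalation PBPK model used throughout the package.
#' The model consists of a gas-exchange/arterial-blood compartment, a
#' venous-blood compartment, and an arbitrary set of perfused tissue
#' compartments connected in parallel between the arterial and venous
#' pools. Cyanide elimination (detoxification to thiocyanate) is
#' first-order, with a per-compartment rate constant.
#'
#' @param volumes named numeric vector of compartment volumes (L). Must
#'   contain entries for `arterial` and `venous` plus every tissue.
#' @param flows named numeric vector of tissue perfusion rates (L/min),
#'   one entry per tissue compartment (i.e. every compartment except
#'   `arterial` and `venous`). Must sum to `cardiac_output`.
#' @param partitions named numeric vector of tissue:blood partition
#'   coefficients (dimensionless), one entry per tissue compartment.
#' @param k_met named numeric vector of first-order CN elimination rate
#'   constants (1/min). Compartments not named default to 0.
#' @param cardiac_output total cardiac output (L/min).
#' @param alveolar_ventilation alveolar ventilation (L/min).
#' @param blood_air_partition blood:air partition coefficient of HCN
#'   (dimensionless). Controls both pulmonary uptake and exhalation.
#' @param arterial,venous names of the designated arterial and venous
#'   blood compartments. Must be distinct and present in `volumes`.
#' @param body_weight body weight (kg); bookkeeping only, not used by the
#'   mass balance.
#' @param molecular_weight molecular weight of HCN (g/mol).
#' @param molar_volume molar gas volume (L/mol) at the reference
#'   temperature used for the ppm conversion; 24.45 L/mol corresponds to
#'   25 degrees C and 1 atm.
#'
#' @return An object of class `pbpk_params`: a list with components
#'   `compartments`, `tissues`, `arterial`, `venous`, `volumes`, `flows`,
#'   `partitions`, `k_met` and the scalar constants above.
#'
#' @seealso [default_pbpk_params()] for the packaged reference-human set,
#'   [simulate_exposure()] for the forward model.
#' @export
pbpk_params <- function(volumes,
                        flows,
                        partitions,
                        k_met = numeric(0),
                        cardiac_output,
                        alveolar_ventilation,
                        blood_air_partition,
                        arterial = "arterial",
                        venous = "venous",
                        body_weight = 70,
                        molecular_weight = 27.03,
                        molar_volume = 24.45) {
  volumes <- unlist(volumes)
  flows <- unlist(flows)
  partitions <- unlist(partitions)
  k_met <- unlist(k_met)
  stopifnot(is.numeric(volumes), !is.null(names(volumes)))
  compartments <- names(volumes)
  tissues <- setdiff(compartments, c(arterial, venous))

  k_full <- stats::setNames(numeric(length(compartments)), compartments)
  if (length(k_met)) {
    unknown <- setdiff(names(k_met), compartments)
    if (length(unknown)) {
      stop("k_met given for unknown compartment(s): ",
           paste(unknown, collapse = ", "))
    }
    k_full[names(k_met)] <- k_met
  }

  obj <- structure(
    list(
      compartments = compartments,
      tissues = tissues,
      arterial = arterial,
      venous = venous,
      volumes = volumes,
      flows = flows[tissues],
      partitions = partitions[tissues],
      k_met = k_full,
      cardiac_output = cardiac_output,
      alveolar_ventilation = alveolar_ventilation,
      blood_air_partition = blood_air_partition,
      body_weight = body_weight,
      molecular_weight = molecular_weight,
      molar_volume = molar_volume
    ),
    class = "pbpk_params"
  )
  validate_pbpk_params(obj)
}

#' Validate a PBPK parameter set
#'
#' Checks structural invariants: strictly positive volumes, flows and
#' partition coefficients; non-negative metabolic rate constants; distinct
#' arterial and venous compartments; and tissue flows summing to cardiac
#' output (relative tolerance 1e-9).
#'
#' @param p a `pbpk_params` object.
#' @return `p`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_pbpk_params <- function(p) {
  stopifnot(inherits(p, "pbpk_params"))
  if (!(p$arterial %in% p$compartments) || !(p$venous %in% p$compartments)) {
    stop("arterial and venous compartments must be present in 'volumes'")
  }
  if (identical(p$arterial, p$venous)) {
    stop("arterial and venous compartments must be distinct")
  }
  if (any(!is.finite(p$volumes)) || any(p$volumes <= 0)) {
    stop("all compartment volumes must be finite and strictly positive")
  }
  if (length(p$tissues) == 0) {
    stop("at least one perfused tissue compartment is required")
  }
  if (any(is.na(p$flows)) || any(p$flows <= 0)) {
    stop("every tissue needs a finite, strictly positive blood flow")
  }
  if (any(is.na(p$partitions)) || any(p$partitions <= 0)) {
    stop("every tissue needs a finite, strictly positive partition coefficient")
  }
  if (any(p$k_met < 0)) stop("metabolic rate constants must be non-negative")
  for (field in c("cardiac_output", "alveolar_ventilation",
                  "blood_air_partition", "molecular_weight", "molar_volume")) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", field))
    }
  }
  rel <- abs(sum(p$flows) - p$cardiac_output) / p$cardiac_output
  if (rel > 1e-9) {
    stop(sprintf(
      "tissue blood flows (%.6f L/min) must sum to cardiac output (%.6f L/min)",
      sum(p$flows), p$cardiac_output))
  }
  invisible(p)
}

#' Generic reference-human PBPK parameter set
#'
#' The packaged default parameterisation: a synthetic generic adult-human
#' set assembled from standard physiological reference tables (compartment
#' volumes and perfusion fractions of the kind tabulated by Brown et al.,
#' 1997), with cyanide-specific constants (blood:air partition, near-unity
#' tissue:blood partitioning of the cyanide ion, first-order hepatic
#' detoxification to thiocyanate) set to round literature-scale values.
#' It is a generic construction, deliberately labelled non-canonical: it is
#' not a published HCN-specific calibration, and absolute concentration
#' predictions carry the corresponding uncertainty. All values can be
#' overridden via [pbpk_params()] or a YAML configuration file
#' ([read_pbpk_params()]); the same file format ships as
#' `inst/extdata/pbpk_human_generic.yaml`.
#'
#' Compartments: `arterial` (lung + systemic arterial blood, 1.8 L),
#' `venous` (3.7 L), `liver` (1.82 L), `kidney` (0.31 L), `muscle` (28 L),
#' `fat` (13.3 L), `rich` (remaining richly perfused viscera, 3 L).
#' Cardiac output 6.2 L/min, alveolar ventilation 5.4 L/min (rest),
#' blood:air partition 200, hepatic k_met 0.35/min.
#'
#' @return a validated `pbpk_params` object.
#' @export
default_pbpk_params <- function() {
  pbpk_params(
    volumes = c(arterial = 1.8, venous = 3.7, liver = 1.82, kidney = 0.31,
                muscle = 28.0, fat = 13.3, rich = 3.0),
    flows = c(liver = 1.55, kidney = 1.18, muscle = 1.05, fat = 0.31,
              rich = 2.11),
    partitions = c(liver = 1.0, kidney = 1.0, muscle = 1.0, fat = 0.25,
                   rich = 1.0),
    k_met = c(liver = 0.35),
    cardiac_output = 6.2,
    alveolar_ventilation = 5.4,
    blood_air_partition = 200,
    body_weight = 70,
    molecular_weight = 27.03,
    molar_volume = 24.45
  )
}

#' @export
print.pbpk_params <- function(x, ...) {
  cat("PBPK parameter set (", length(x$compartments), " compartments)\n",
      sep = "")
  cat("  blood: arterial = '", x$arterial, "' (", x$volumes[[x$arterial]],
      " L), venous = '", x$venous, "' (", x$volumes[[x$venous]], " L)\n",
      sep = "")
  df <- data.frame(
    volume_L = x$volumes[x$tissues],
    flow_L_min = x$flows[x$tissues],
    partition = x$partitions[x$tissues],
    k_met_per_min = x$k_met[x$tissues]
  )
  print(df, ...)
  cat(sprintf(
    "  cardiac output %.3g L/min | alveolar ventilation %.3g L/min | blood:air %.3g\n",
    x$cardiac_output, x$alveolar_ventilation, x$blood_air_partition))
  cat(sprintf("  MW %.4g g/mol | molar volume %.4g L/mol | body weight %.3g kg\n",
              x$molecular_weight, x$molar_volume, x$body_weight))
  invisible(x)
}

#' Convert a gas-phase ppm (v/v) concentration to mass concentration
#'
#' Unit bridge between the exposure scenario (ppm of HCN in inspired air)
#' and the mass-balance ODEs (mg HCN per litre of air):
#' `ppm * molecular_weight / (molar_volume * 1000)`.
#'
#' @param ppm volume fraction in parts per million; must be non-negative.
#' @param params a `pbpk_params` object supplying `molecular_weight` and
#'   `molar_volume`.
#' @param temperature_celsius optional override: when given, the molar
#'   volume is recomputed from the ideal-gas law at 1 atm
#'   (22.414 L/mol x T/273.15 K) instead of `params$molar_volume`.
#' @return mass concentration in mg/L (equivalently g/m3 / 1000).
#' @examples
#' p <- default_pbpk_params()
#' ppm_to_air_concentration(5000, p)   # about 5.53 mg/L
#' @export
ppm_to_air_concentration <- function(ppm, params, temperature_celsius = NULL) {
  if (any(!is.finite(ppm)) || any(ppm < 0)) {
    stop("'ppm' must be finite and non-negative")
  }
  vm <- if (is.null(temperature_celsius)) {
    params$molar_volume
  } else {
    22.414 * (273.15 + temperature_celsius) / 273.15
  }
  ppm * params$molecular_weight / (vm * 1000)
}

#' Read / write a PBPK parameter configuration file
#'
#' YAML schema: top-level keys `cardiac_output`, `alveolar_ventilation`,
#' `blood_air_partition`, `body_weight`, `molecular_weight`,
#' `molar_volume`, `arterial`, `venous`, `blood` (mapping of the two blood
#' compartments to volumes) and `tissues` (mapping of tissue name to
#' `volume`, `flow`, `partition`, `k_met`).
#'
#' @param path file path.
#' @return `read_pbpk_params` returns a validated `pbpk_params` object;
#'   `write_pbpk_params` returns `path` invisibly.
#' @export
read_pbpk_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  tissues <- cfg$tissues
  tn <- names(tissues)
  vols <- c(
    stats::setNames(as.numeric(unlist(cfg$blood)), names(cfg$blood)),
    stats::setNames(vapply(tissues, function(t) as.numeric(t$volume), 0), tn)
  )
  k <- vapply(tissues, function(t) as.numeric(t$k_met %||% 0), 0)
  pbpk_params(
    volumes = vols,
    flows = stats::setNames(vapply(tissues, function(t) as.numeric(t$flow), 0), tn),
    partitions = stats::setNames(
      vapply(tissues, function(t) as.numeric(t$partition), 0), tn),
    k_met = stats::setNames(k, tn),
    cardiac_output = cfg$cardiac_output,
    alveolar_ventilation = cfg$alveolar_ventilation,
    blood_air_partition = cfg$blood_air_partition,
    arterial = cfg$arterial %||% "arterial",
    venous = cfg$venous %||% "venous",
    body_weight = cfg$body_weight %||% 70,
    molecular_weight = cfg$molecular_weight %||% 27.03,
    molar_volume = cfg$molar_volume %||% 24.45
  )
}

#' @rdname read_pbpk_params
#' @param params a `pbpk_params` object to serialise.
#' @export
write_pbpk_params <- function(params, path) {
  validate_pbpk_params(params)
  tissues <- lapply(params$tissues, function(nm) {
    list(volume = unname(params$volumes[[nm]]),
         flow = unname(params$flows[[nm]]),
         partition = unname(params$partitions[[nm]]),
         k_met = unname(params$k_met[[nm]]))
  })
  names(tissues) <- params$tissues
  cfg <- list(
    arterial = params$arterial,
    venous = params$venous,
    cardiac_output = unname(params$cardiac_output),
    alveolar_ventilation = unname(params$alveolar_ventilation),
    blood_air_partition = unname(params$blood_air_partition),
    body_weight = unname(params$body_weight),
    molecular_weight = unname(params$molecular_weight),
    molar_volume = unname(params$molar_volume),
    blood = stats::setNames(
      list(unname(params$volumes[[params$arterial]]),
           unname(params$volumes[[params$venous]])),
      c(params$arterial, params$venous)),
    tissues = tissues
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
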