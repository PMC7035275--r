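#' Gas species registry
#'
#' The registry maps gas names to molar masses (g mol-1) and to the
#' element-mass scaling used when fluxes are reported as CH4-C or N2O-N
#' rather than as full molecules. The defaults cover the three species a
#' combined stem (GC) and soil (CRDS analyser) chamber campaign measures.
#'
#' @param extra optional tibble/data.frame with columns `gas`, `molar_mass`
#'   and optionally `element_mass` appended to (or overriding) the defaults.
#'
#' @return A tibble with columns `gas`, `molar_mass` (g mol-1) and
#'   `element_mass` (g mol-1 of the reported element: C for CH4 and CO2,
#'   N2 for N2O).
#' @examples
#' gas_registry()
#' @export
gas_registry <- function(extra = NULL) {
  reg <- tibble::tibble(
    gas = c("CH4", "N2O", "CO2"),
    molar_mass = c(16.043, 44.013, 44.010),
    # element basis: C in CH4/CO2, the two N in N2O
    element_mass = c(12.011, 28.014, 12.011)
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    if (!all(c("gas", "molar_mass") %in% names(extra))) {
      stop_stemflux("registry", "`extra` must have columns `gas` and `molar_mass`.")
    }
    if (!"element_mass" %in% names(extra)) extra$element_mass <- extra$molar_mass
    reg <- dplyr::bind_rows(extra, reg)
    reg <- reg[!duplicated(reg$gas), ]
  }
  if (any(!is.finite(reg$molar_mass)) || any(reg$molar_mass <= 0)) {
    stop_stemflux("registry", "Molar masses must be positive and finite.")
  }
  reg
}

gas_molar_mass <- function(gas, registry = gas_registry()) {
  idx <- match(gas, registry$gas)
  if (anyNA(idx)) {
    stop_stemflux(
      "unknown_gas",
      paste0("Gas not in registry: ", paste(unique(gas[is.na(idx)]), collapse = ", "))
    )
  }
  registry$molar_mass[idx]
}

check_conditions <- function(temp_k, pressure_pa) {
  if (any(!is.finite(temp_k)) || any(temp_k <= 0) ||
      any(!is.finite(pressure_pa)) || any(pressure_pa <= 0)) {
    stop_stemflux(
      "invalid_conditions",
      "Temperature and pressure must be finite and positive (K, Pa)."
    )
  }
  invisible(TRUE)
}

#' Convert a mole fraction to a mass concentration via the ideal gas law
#'
#' A mixing ratio of `x` ppm (umol mol-1) at temperature `T` and pressure
#' `P` corresponds to `x * M * P / (R * T)` micrograms of gas per cubic
#' metre, with `M` the molar mass and `R` the universal gas constant.
#' This is the conversion applied to chamber headspace concentrations
#' before flux fitting.
#'
#' @param x mole fraction(s) in ppm (umol mol-1); must be non-negative.
#' @param gas gas name(s) resolved through `registry`.
#' @param temp_k air temperature in kelvin.
#' @param pressure_pa pressure in pascal; defaults to [STANDARD_PRESSURE].
#' @param registry gas registry, see [gas_registry()].
#'
#' @return Mass concentration(s) in ug m-3.
#' @examples
#' ppm_to_mass(1.9, "CH4", temp_k = 293.15)
#' @export
ppm_to_mass <- function(x, gas, temp_k, pressure_pa = STANDARD_PRESSURE,
                        registry = gas_registry()) {
  check_conditions(temp_k, pressure_pa)
  if (any(x < 0, na.rm = TRUE)) {
    stop_stemflux("invalid_conditions", "Mole fractions must be non-negative.")
  }
  M <- gas_molar_mass(gas, registry)
  x * M * pressure_pa / (GAS_CONSTANT * temp_k)
}

#' Convert a mass concentration back to a mole fraction
#'
#' Exact inverse of [ppm_to_mass()]; used by the synthetic closure
#' generator, whose forward model lives in mass-concentration space.
#'
#' @param c_ugm3 mass concentration(s) in ug m-3.
#' @inheritParams ppm_to_mass
#' @return Mole fraction(s) in ppm.
#' @export
mass_to_ppm <- function(c_ugm3, gas, temp_k, pressure_pa = STANDARD_PRESSURE,
                        registry = gas_registry()) {
  check_conditions(temp_k, pressure_pa)
  M <- gas_molar_mass(gas, registry)
  c_ugm3 * GAS_CONSTANT * temp_k / (M * pressure_pa)
}

#' Convert a closure series from ppm to mass concentration
#'
#' Applies [ppm_to_mass()] elementwise at each sample's recorded
#' temperature and pressure, leaving the sampling grid untouched.
#'
#' @param closures long-format closure tibble (see [read_closures()] for the
#'   schema: `chamber_id`, `closure_start`, `period`, `plot_id`,
#'   `t_seconds`, `gas`, `ppm`, `temp_k`, `pressure_pa`).
#' @param gases gases to convert; defaults to every gas present. Requesting
#'   a gas absent from the series is an error.
#' @param registry gas registry.
#'
#' @return The input rows for the requested gases with an added
#'   `conc_ugm3` column.
#' @export
convert_series <- function(closures, gases = NULL, registry = gas_registry()) {
  closures <- validate_closures(closures)
  if (is.null(gases)) gases <- unique(closures$gas)
  missing_gas <- setdiff(gases, unique(closures$gas))
  if (length(missing_gas) > 0) {
    stop_stemflux(
      "missing_gas",
      paste0("Gas channel(s) not present in series: ", paste(missing_gas, collapse = ", "))
    )
  }
  out <- closures[closures$gas %in% gases, , drop = FALSE]
  out$conc_ugm3 <- ppm_to_mass(out$ppm, out$gas, out$temp_k, out$pressure_pa, registry)
  out
}

#' Scaling factor from full-molecule flux to element-mass flux
#'
#' Fluxes are expressed as full molecules (ug CH4, ug N2O) by default;
#' `unit_mode = "element"` rescales to CH4-C / N2O-N / CO2-C mass for
#' cross-study comparison.
#'
#' @param gas gas name(s).
#' @param unit_mode `"molecule"` (factor 1) or `"element"`.
#' @param registry gas registry.
#' @return Multiplicative factor(s) to apply to a full-molecule flux.
#' @export
flux_unit_factor <- function(gas, unit_mode = c("molecule", "element"),
                             registry = gas_registry()) {
  unit_mode <- match.arg(unit_mode)
  if (unit_mode == "molecule") return(rep(1, length(gas)))
  idx <- match(gas, registry$gas)
  if (anyNA(idx)) {
    stop_stemflux("unknown_gas", paste0("Gas not in registry: ", paste(gas[is.na(idx)], collapse = ", ")))
  }
  registry$element_mass[idx] / registry$molar_mass[idx]
}
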