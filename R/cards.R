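#' Solute property card
#'
#' Pure-component constants of the solid solute used by the equation-of-state
#' route (critical constants, acentric factor) and by the solid-fugacity
#' reference (melting temperature, fusion enthalpy, solid molar volume).
#'
#' @param name solute name.
#' @param formula empirical formula; when `molar_mass` is `NULL` the molar
#'   mass is computed from it with IUPAC 2021 atomic weights.
#' @param molar_mass g mol^-1; overrides the formula-derived value.
#' @param lambda_max UV detection wavelength in nm (metadata only).
#' @param melt_temperature melting temperature T_m, K.
#' @param fusion_enthalpy molar enthalpy of fusion, kJ mol^-1.
#' @param critical_temperature T_c, K.
#' @param critical_pressure P_c, MPa.
#' @param acentric_factor dimensionless.
#' @param solid_molar_volume solid molar volume, cm^3 mol^-1.
#' @return an object of class `solute_card`.
#' @export
solute_card <- function(name, formula, molar_mass = NULL, lambda_max = NA_real_,
                        melt_temperature, fusion_enthalpy,
                        critical_temperature, critical_pressure,
                        acentric_factor, solid_molar_volume) {
  if (is.null(molar_mass)) molar_mass <- molar_mass(formula)
  card <- structure(list(
    name = as.character(name), formula = as.character(formula),
    molar_mass = molar_mass, lambda_max = lambda_max,
    melt_temperature = melt_temperature, fusion_enthalpy = fusion_enthalpy,
    critical_temperature = critical_temperature,
    critical_pressure = critical_pressure,
    acentric_factor = acentric_factor,
    solid_molar_volume = solid_molar_volume
  ), class = "solute_card")
  validate_solute_card(card)
}

#' @export
print.solute_card <- function(x, ...) {
  cat(sprintf("<solute_card> %s (%s), M = %.2f g/mol\n", x$name, x$formula, x$molar_mass))
  cat(sprintf("  Tm = %.2f K, dHm = %.2f kJ/mol, Vs = %.2f cm3/mol\n",
              x$melt_temperature, x$fusion_enthalpy, x$solid_molar_volume))
  cat(sprintf("  Tc = %.2f K, Pc = %.4f MPa, omega = %.4f\n",
              x$critical_temperature, x$critical_pressure, x$acentric_factor))
  invisible(x)
}

validate_solute_card <- function(card) {
  for (f in c("molar_mass", "melt_temperature", "fusion_enthalpy",
              "critical_temperature", "critical_pressure", "solid_molar_volume")) {
    .chk_num(card[[f]], f, positive = TRUE)
  }
  .chk_num(card$acentric_factor, "acentric_factor")
  if (card$melt_temperature >= card$critical_temperature) {
    stop_scsolub("validation_error",
                 "melt_temperature must be below critical_temperature")
  }
  card
}

#' Solvent property card
#'
#' Pure-component constants of the supercritical solvent.  The default is
#' carbon dioxide with standard literature constants; all values can be
#' overridden.
#'
#' @param molar_mass g mol^-1.
#' @param critical_temperature K.
#' @param critical_pressure MPa.
#' @param acentric_factor dimensionless.
#' @param name solvent name.
#' @return an object of class `solvent_card`.
#' @export
solvent_card <- function(molar_mass = .CO2_CONSTANTS$molar_mass,
                         critical_temperature = .CO2_CONSTANTS$critical_temperature,
                         critical_pressure = .CO2_CONSTANTS$critical_pressure,
                         acentric_factor = .CO2_CONSTANTS$acentric_factor,
                         name = "CO2") {
  card <- structure(list(
    name = as.character(name), molar_mass = molar_mass,
    critical_temperature = critical_temperature,
    critical_pressure = critical_pressure,
    acentric_factor = acentric_factor
  ), class = "solvent_card")
  for (f in c("molar_mass", "critical_temperature", "critical_pressure",
              "acentric_factor")) {
    .chk_num(card[[f]], f, positive = TRUE)
  }
  card
}

#' @export
print.solvent_card <- function(x, ...) {
  cat(sprintf("<solvent_card> %s, M = %.2f g/mol, Tc = %.2f K, Pc = %.3f MPa, omega = %.4f\n",
              x$name, x$molar_mass, x$critical_temperature, x$critical_pressure,
              x$acentric_factor))
  invisible(x)
}

#' Read a property card from JSON
#'
#' @param path JSON file with the card fields.
#' @param type `"solute"` or `"solvent"`.
#' @return a `solute_card` or `solvent_card`.
#' @export
read_card <- function(path, type = c("solute", "solvent")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_scsolub("io_error", sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (type == "solute") {
    solute_card(
      name = x$name, formula = x$formula, molar_mass = x$molar_mass,
      lambda_max = x$lambda_max %||% NA_real_,
      melt_temperature = x$melt_temperature, fusion_enthalpy = x$fusion_enthalpy,
      critical_temperature = x$critical_temperature,
      critical_pressure = x$critical_pressure,
      acentric_factor = x$acentric_factor,
      solid_molar_volume = x$solid_molar_volume
    )
  } else {
    solvent_card(
      molar_mass = x$molar_mass,
      critical_temperature = x$critical_temperature,
      critical_pressure = x$critical_pressure,
      acentric_factor = x$acentric_factor,
      name = x$name %||% "solvent"
    )
  }
}

#' Write a property card to JSON
#'
#' @param card a `solute_card` or `solvent_card`.
#' @param path output file.
#' @export
write_card <- function(card, path) {
  jsonlite::write_json(unclass(card), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
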