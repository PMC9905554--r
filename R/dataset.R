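## Canonical column header of the dataset CSV dialect.  Units are fixed at the
## storage boundary: K, MPa, kg m^-3; mole fraction and its uncertainties are
## dimensionless; mass solubility is g L^-1 (numerically equal to kg m^-3).
.DATASET_COLUMNS <- c("temperature_K", "pressure_MPa", "co2_density_kg_m3",
                      "mole_fraction", "mass_solubility_g_L", "std_y",
                      "expanded_uncertainty_y")
.DATASET_REQUIRED <- .DATASET_COLUMNS[1:4]

#' Assemble a solubility dataset
#'
#' Bundles equilibrium solubility records with the solute and solvent
#' property cards.  Records are validated (positivity, mole-fraction bounds,
#' no duplicate (T, P) pairs) and sorted by temperature then pressure.  When
#' `mass_solubility_g_L` is present its consistency with the mole fraction
#' through the sampling-loop relation is checked to 2 % relative tolerance.
#'
#' @param records data.frame with the canonical columns (see
#'   [load_dataset()]); the three uncertainty columns are optional.
#' @param solute a [solute_card()].
#' @param solvent a [solvent_card()].
#' @param provenance free-text description of where the records came from.
#' @param check_consistency check the S - y loop relation (default TRUE).
#' @return object of class `sc_dataset`: list with elements `records`
#'   (data.frame), `solute`, `solvent`, `provenance`.
#' @export
solubility_dataset <- function(records, solute, solvent = solvent_card(),
                               provenance = "user", check_consistency = TRUE) {
  stopifnot(inherits(solute, "solute_card"), inherits(solvent, "solvent_card"))
  records <- as.data.frame(records)
  missing_cols <- setdiff(.DATASET_REQUIRED, names(records))
  if (length(missing_cols)) {
    stop_scsolub("schema_error",
                 sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(.DATASET_COLUMNS, names(records))) records[[col]] <- NA_real_
  records <- records[.DATASET_COLUMNS]
  if (nrow(records) == 0L) {
    stop_scsolub("schema_error", "dataset has no records")
  }

  .check_records(records, solute, solvent, check_consistency)
  ord <- order(records$temperature_K, records$pressure_MPa)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, solute = solute, solvent = solvent,
                 provenance = provenance),
            class = "sc_dataset")
}

.check_records <- function(records, solute, solvent, check_consistency) {
  chk <- function(ok, rule) {
    bad <- which(!ok)
    if (length(bad)) {
      stop_scsolub("validation_error",
                   sprintf("record %d violates: %s", bad[1], rule),
                   row = bad[1], rule = rule)
    }
  }
  with(records, {
    chk(is.finite(temperature_K) & temperature_K > 0, "temperature > 0")
    chk(is.finite(pressure_MPa) & pressure_MPa > 0, "pressure > 0")
    chk(is.finite(co2_density_kg_m3) & co2_density_kg_m3 > 0, "co2_density > 0")
    chk(is.finite(mole_fraction) & mole_fraction > 0 & mole_fraction < 1,
        "0 < mole_fraction < 1")
  })
  key <- paste(records$temperature_K, records$pressure_MPa)
  if (anyDuplicated(key)) {
    stop_scsolub("validation_error",
                 sprintf("duplicate (temperature, pressure) pair: %s",
                         key[duplicated(key)][1]))
  }
  if (check_consistency && any(is.finite(records$mass_solubility_g_L))) {
    i <- is.finite(records$mass_solubility_g_L)
    s_loop <- mole_fraction_to_mass_solubility(
      records$mole_fraction[i], records$co2_density_kg_m3[i],
      solvent$molar_mass, solute$molar_mass)
    dev <- abs(records$mass_solubility_g_L[i] - s_loop) / s_loop
    if (any(dev > 0.02)) {
      j <- which(i)[which.max(dev)]
      stop_scsolub("validation_error",
                   sprintf(paste0("record %d violates: mass solubility and mole",
                                  " fraction inconsistent through the loop",
                                  " relation (%.1f%% relative)"),
                           j, 100 * max(dev)), row = j)
    }
  }
  invisible(TRUE)
}

#' Mass solubility from mole fraction through the sampling-loop relation
#'
#' Inverts the measurement reduction: given the equilibrium mole fraction and
#' the solvent density in the loop, returns the mass solubility
#' S = y/(1-y) * rho * M2/M1 in g L^-1.
#'
#' @param y solute mole fraction.
#' @param rho solvent density, kg m^-3.
#' @param m_solvent,m_solute molar masses, g mol^-1.
#' @export
mole_fraction_to_mass_solubility <- function(y, rho, m_solvent, m_solute) {
  y / (1 - y) * rho * m_solute / m_solvent
}

#' @export
print.sc_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("<sc_dataset> %d records: T %g-%g K, P %g-%g MPa (%s in %s)\n",
              nrow(r), min(r$temperature_K), max(r$temperature_K),
              min(r$pressure_MPa), max(r$pressure_MPa),
              x$solute$name, x$solvent$name))
  cat(sprintf("  y range %.3g - %.3g; provenance: %s\n",
              min(r$mole_fraction), max(r$mole_fraction), x$provenance))
  invisible(x)
}

#' Load a solubility dataset from CSV or JSON
#'
#' The CSV dialect is UTF-8, comma-separated, dot decimal, one header row with
#' the canonical columns `temperature_K, pressure_MPa, co2_density_kg_m3,
#' mole_fraction, mass_solubility_g_L, std_y, expanded_uncertainty_y` (the
#' last three optional).  The JSON format is an object with fields `records`
#' (array of records keyed by the same names), `solute`, `solvent`,
#' `provenance`.
#'
#' @param path input file.
#' @param format `"csv"` or `"json"`.  For CSV the property cards must be
#'   supplied through `solute` / `solvent`.
#' @param solute,solvent property cards (CSV input only).
#' @param provenance free text.
#' @return an `sc_dataset`.
#' @export
load_dataset <- function(path, format = c("csv", "json"), solute = NULL,
                         solvent = solvent_card(), provenance = path) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_scsolub("io_error", sprintf("file not found: %s", path))
  if (format == "csv") {
    if (is.null(solute)) {
      stop_scsolub("usage_error", "CSV datasets need a solute_card via 'solute'")
    }
    records <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE),
      error = function(e) stop_scsolub("schema_error",
                                       sprintf("cannot read CSV: %s", conditionMessage(e))))
    if (nrow(records) == 0L || !all(.DATASET_REQUIRED %in% names(records))) {
      missing_cols <- setdiff(.DATASET_REQUIRED, names(records))
      stop_scsolub("schema_error",
                   if (length(missing_cols))
                     sprintf("missing required column(s): %s",
                             paste(missing_cols, collapse = ", "))
                   else "dataset has no records")
    }
    solubility_dataset(records, solute, solvent, provenance)
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(x$records) || is.null(x$solute)) {
      stop_scsolub("schema_error", "JSON dataset needs 'records' and 'solute'")
    }
    sol <- do.call(solute_card, x$solute[setdiff(names(x$solute), "")])
    slv <- if (!is.null(x$solvent)) do.call(solvent_card, x$solvent) else solvent_card()
    solubility_dataset(as.data.frame(x$records), sol, slv,
                       provenance = x$provenance %||% provenance)
  }
}

#' Write a solubility dataset
#'
#' @param dataset an `sc_dataset`.
#' @param path output file.
#' @param format `"csv"` (records only) or `"json"` (records + cards).
#' @export
write_dataset <- function(dataset, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "sc_dataset"))
  if (format == "csv") {
    utils::write.csv(dataset$records, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(records = dataset$records,
           solute = unclass(dataset$solute),
           solvent = unclass(dataset$solvent),
           provenance = dataset$provenance),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' The packaged palbociclib / supercritical CO2 study
#'
#' Returns the transcribed palbociclib solubility study: 24 equilibrium
#' records on a 4 temperature x 6 pressure grid (308-338 K, 12-27 MPa) with
#' NIST CO2 densities, replicate standard deviations and expanded
#' uncertainties (k = 2), plus the palbociclib and CO2 property cards.  The
#' solute molar mass is derived from the empirical formula C24H29N7O2.
#'
#' The stored mass-solubility column is recomputed from the authoritative
#' (y, rho) pairs through the sampling-loop relation; see
#' [flag_inconsistent_solubility()] for comparison against independently
#' reported values.
#'
#' @return an `sc_dataset` with 24 records.
#' @export
builtin_palbociclib_study <- function() {
  csv <- system.file("extdata", "palbociclib_scco2.csv", package = "scsolub",
                     mustWork = TRUE)
  card <- system.file("extdata", "palbociclib.json", package = "scsolub",
                      mustWork = TRUE)
  co2 <- system.file("extdata", "co2.json", package = "scsolub", mustWork = TRUE)
  load_dataset(csv, "csv", solute = read_card(card, "solute"),
               solvent = read_card(co2, "solvent"),
               provenance = "palbociclib/ScCO2 equilibrium study (packaged)")
}

#' Flag mass-solubility values inconsistent with the loop relation
#'
#' Compares externally reported mass solubilities against the values implied
#' by the dataset's (y, rho) pairs through the sampling-loop relation and
#' flags rows deviating more than `tol` relative.
#'
#' @param dataset an `sc_dataset`.
#' @param reported_S vector of reported mass solubilities, g L^-1, in the
#'   dataset's record order.
#' @param tol relative tolerance (default 0.02).
#' @return data.frame with T, P, reported and loop-relation S, relative
#'   deviation and a logical `flagged`.
#' @export
flag_inconsistent_solubility <- function(dataset, reported_S, tol = 0.02) {
  stopifnot(inherits(dataset, "sc_dataset"))
  r <- dataset$records
  if (length(reported_S) != nrow(r)) {
    stop_scsolub("usage_error", "reported_S must have one value per record")
  }
  s_loop <- mole_fraction_to_mass_solubility(
    r$mole_fraction, r$co2_density_kg_m3,
    dataset$solvent$molar_mass, dataset$solute$molar_mass)
  dev <- (reported_S - s_loop) / s_loop
  data.frame(temperature_K = r$temperature_K, pressure_MPa = r$pressure_MPa,
             reported_S = reported_S, loop_S = s_loop, rel_dev = dev,
             flagged = abs(dev) > tol)
}
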