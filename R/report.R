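## End-to-end study orchestration: fit the selected semi-empirical models and
## EoS mixing rules, extract enthalpies, run the self-consistency tests and
## emit machine-readable report tables.

#' Semi-empirical fit report table
#'
#' @param fits list of `se_fit` objects.
#' @return data.frame with one row per model: parameters a0..a7 (NA where the
#'   model has fewer) and AARD%.
#' @export
table4_report <- function(fits) {
  rows <- lapply(fits, function(f) {
    a <- rep(NA_real_, 8)
    a[seq_along(f$parameters)] <- f$parameters
    data.frame(model = f$spec$model_id, t(stats::setNames(a, paste0("a", 0:7))),
               aard_percent = f$aard_percent)
  })
  do.call(rbind, rows)
}

#' EoS fit report table
#'
#' @param fits list of `eos_fit` objects.
#' @return data.frame with mixing rule, binary parameters, AARD% and ALD-y.
#' @export
table6_report <- function(fits) {
  rows <- lapply(fits, function(f) {
    data.frame(
      mixing_rule = f$rule$kind,
      k12 = f$rule$k12 %||% NA_real_,
      u12 = if (!is.null(f$rule$ge_model$u12)) f$rule$ge_model$u12 else NA_real_,
      u21 = if (!is.null(f$rule$ge_model$u21)) f$rule$ge_model$u21 else NA_real_,
      aard_percent = f$aard_percent,
      ald_y = f$ald_y,
      n_failed = f$n_failed
    )
  })
  do.call(rbind, rows)
}

#' Run the full solubility study
#'
#' Orchestrates the pipeline on a dataset: semi-empirical fits (AARD
#' objective), dissolution/vaporization/solvation enthalpies from the
#' Chrastil and Bartle fits, Chrastil and MST self-consistency tests, MST
#' crossover location, and EoS fits (ALD-y objective).  Outputs are returned
#' as a report bundle and optionally written as CSV/JSON.
#'
#' @param dataset `"builtin"`, a path to a dataset file, or an `sc_dataset`.
#' @param models semi-empirical model ids to fit (default all ten); may be
#'   empty only if `eos_rules` is not.
#' @param eos_rules EoS mixing-rule kinds to fit (default none; fitting the
#'   Wong-Sandler rule takes substantially longer than vdW).
#' @param n_restarts,seed optimiser settings (see [fit_model()]).
#' @param eos_starts multistart count for the 2-D EoS searches.
#' @param output_dir if non-NULL, writes `table4.csv`, `table6.csv`,
#'   `enthalpies.json`, `consistency.csv` and `summary.json` there.
#' @param solute,solvent cards for file-based datasets.
#' @return list of class `study_report` with elements `table4`, `fits`,
#'   `enthalpy`, `consistency`, `crossover_mst_MPa`, `table6`, `eos_fits`.
#' @export
run_study <- function(dataset = "builtin", models = se_model_ids(),
                      eos_rules = character(), n_restarts = 64L,
                      seed = 20230207L, eos_starts = 8L, output_dir = NULL,
                      solute = NULL, solvent = solvent_card()) {
  if (!length(models) && !length(eos_rules)) {
    stop_scsolub("usage_error", "select at least one model to fit")
  }
  bad <- setdiff(models, se_model_ids())
  if (length(bad)) {
    stop_scsolub("usage_error",
                 sprintf("unknown model id(s): %s", paste(bad, collapse = ", ")))
  }
  ds <- if (inherits(dataset, "sc_dataset")) dataset
  else if (identical(dataset, "builtin")) builtin_palbociclib_study()
  else load_dataset(dataset, if (grepl("\\.json$", dataset)) "json" else "csv",
                    solute = solute, solvent = solvent)

  fits <- lapply(models, function(m) fit_model(m, ds, n_restarts = n_restarts,
                                               seed = seed))
  names(fits) <- models

  enth <- NULL
  if (all(c("chrastil", "bartle") %in% models)) {
    enth <- enthalpies(fits$chrastil, fits$bartle)
  }
  consist <- list()
  if ("chrastil" %in% models) {
    consist$chrastil <- consistency_test("chrastil", fits$chrastil, ds)
  }
  if ("mst" %in% models) {
    consist$mst <- consistency_test("mst", fits$mst, ds)
  }
  crossover <- NA_real_
  if ("mst" %in% models) {
    temps <- sort(unique(ds$records$temperature_K))
    if (length(temps) >= 2) {
      crossings <- c()
      for (i in seq_len(length(temps) - 1)) {
        crossings <- c(crossings, crossover_pressure(fits$mst, ds, temps[i],
                                                     temps[i + 1]))
      }
      crossover <- stats::median(crossings, na.rm = TRUE)
    }
  }

  eos_fits <- lapply(eos_rules, function(k) fit_eos(ds, k, n_starts = eos_starts,
                                                    seed = seed))
  names(eos_fits) <- eos_rules

  report <- structure(list(
    dataset = ds,
    table4 = if (length(fits)) table4_report(fits),
    fits = fits,
    enthalpy = enth,
    consistency = consist,
    crossover_mst_MPa = crossover,
    table6 = if (length(eos_fits)) table6_report(eos_fits),
    eos_fits = eos_fits,
    settings = list(models = models, eos_rules = eos_rules,
                    n_restarts = n_restarts, seed = seed)
  ), class = "study_report")

  if (!is.null(output_dir)) .write_report(report, output_dir)
  report
}

.write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$table4)) {
    utils::write.csv(report$table4, file.path(output_dir, "table4.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$table6)) {
    utils::write.csv(report$table6, file.path(output_dir, "table6.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$enthalpy)) {
    jsonlite::write_json(unclass(report$enthalpy),
                         file.path(output_dir, "enthalpies.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (length(report$consistency)) {
    rows <- do.call(rbind, lapply(report$consistency, function(ct) {
      data.frame(model = ct$model_id, slope = ct$slope,
                 intercept = ct$intercept, r_squared = ct$r_squared)
    }))
    utils::write.csv(rows, file.path(output_dir, "consistency.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    n_records = nrow(report$dataset$records),
    models = report$settings$models,
    aard_percent = if (!is.null(report$table4))
      stats::setNames(as.list(report$table4$aard_percent), report$table4$model),
    enthalpy_kJ_mol = if (!is.null(report$enthalpy))
      list(total = report$enthalpy$total,
           vaporization = report$enthalpy$vaporization,
           solvation = report$enthalpy$solvation),
    consistency_r2 = lapply(report$consistency, function(ct) ct$r_squared),
    crossover_mst_MPa = report$crossover_mst_MPa,
    eos = if (!is.null(report$table6))
      lapply(seq_len(nrow(report$table6)), function(i) as.list(report$table6[i, ])),
    seed = report$settings$seed
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(output_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$table4)) {
    cat("  semi-empirical AARD%:\n")
    for (i in seq_len(nrow(x$table4))) {
      cat(sprintf("    %-10s %6.2f\n", x$table4$model[i], x$table4$aard_percent[i]))
    }
  }
  if (!is.null(x$enthalpy)) {
    cat(sprintf("  enthalpies (kJ/mol): total %.2f, vap %.2f, sol %.2f\n",
                x$enthalpy$total, x$enthalpy$vaporization, x$enthalpy$solvation))
  }
  if (length(x$consistency)) {
    for (ct in x$consistency) {
      cat(sprintf("  %s consistency R^2 = %.4f\n", ct$model_id, ct$r_squared))
    }
  }
  if (is.finite(x$crossover_mst_MPa)) {
    cat(sprintf("  MST crossover pressure: %.1f MPa\n", x$crossover_mst_MPa))
  }
  if (!is.null(x$table6)) {
    cat("  EoS fits:\n")
    for (i in seq_len(nrow(x$table6))) {
      cat(sprintf("    %-14s AARD %6.1f%%  ALD-y %.3f\n",
                  x$table6$mixing_rule[i], x$table6$aard_percent[i],
                  x$table6$ald_y[i]))
    }
  }
  invisible(x)
}
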