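## Density-based semi-empirical solubility models.
##
## All ten published forms are linear in their parameters once written in a
## transformed response (ln S, ln y, T ln(yP) or ln(yP/Pref)), which the
## fitter exploits: ordinary least squares in the transformed space provides
## a deterministic starting point, and the AARD objective (relative error in
## mole-fraction space) is then minimised by multistart Nelder-Mead with a
## quasi-Newton polish.
##
## Unit conventions inside the model forms: T in K, density in kg m^-3,
## pressure in bar (records store MPa; the conversion is hard-coded here),
## S in kg m^-3 (numerically g L^-1).

.MPA_TO_BAR <- 10

.SE_MODELS <- list(
  chrastil  = list(n_params = 3L, response = "mass_solubility_kg_m3",
                   label = "Chrastil"),
  mst       = list(n_params = 3L, response = "mole_fraction",
                   label = "Mendez-Santiago-Teja"),
  kj        = list(n_params = 3L, response = "mole_fraction",
                   label = "Kumar-Johnston"),
  bartle    = list(n_params = 3L, response = "mole_fraction",
                   label = "Bartle", reference_pressure = 1,
                   reference_density = 700),
  bian      = list(n_params = 5L, response = "mole_fraction", label = "Bian"),
  garlapati = list(n_params = 5L, response = "mole_fraction",
                   label = "Garlapati-Madras"),
  keshmiri  = list(n_params = 5L, response = "mole_fraction", label = "Keshmiri"),
  khansary  = list(n_params = 5L, response = "mole_fraction", label = "Khansary"),
  sodeifian = list(n_params = 6L, response = "mole_fraction", label = "Sodeifian"),
  belghait  = list(n_params = 8L, response = "mole_fraction", label = "Belghait")
)

#' Available semi-empirical model identifiers
#' @return character vector of model ids.
#' @export
se_model_ids <- function() names(.SE_MODELS)

#' Semi-empirical model specification
#'
#' @param model_id one of `se_model_ids()`.
#' @return object of class `se_model_spec` with fields `model_id`, `n_params`,
#'   `response` and, for the Bartle model, `reference_pressure` (bar) and
#'   `reference_density` (kg m^-3).
#' @export
se_model_spec <- function(model_id) {
  model_id <- match.arg(model_id, se_model_ids())
  m <- .SE_MODELS[[model_id]]
  structure(c(list(model_id = model_id), m), class = "se_model_spec")
}

#' @export
print.se_model_spec <- function(x, ...) {
  cat(sprintf("<se_model_spec> %s (%s), %d parameters, response %s\n",
              x$model_id, x$label, x$n_params, x$response))
  invisible(x)
}

## Design matrix of the linear transformed form; rows follow `records`.
.se_design <- function(spec, records) {
  T_ <- records$temperature_K
  rho <- records$co2_density_kg_m3
  P <- records$pressure_MPa * .MPA_TO_BAR
  if (any(rho <= 0) || any(T_ <= 0) || any(P <= 0)) {
    stop_scsolub("evaluation_error",
                 "model transforms need positive T, P and density")
  }
  switch(spec$model_id,
    chrastil  = cbind(log(rho), 1 / T_, 1),
    mst       = cbind(1, rho, T_),
    kj        = cbind(1, rho, 1 / T_),
    bartle    = cbind(1, rho - spec$reference_density, 1 / T_),
    bian      = cbind(1, 1 / T_, rho / T_, log(rho), rho * log(rho)),
    garlapati = cbind(1, log(rho), rho * log(rho), 1 / T_, log(rho * T_)),
    keshmiri  = cbind(1, 1 / T_, P^2, log(rho), log(rho) / T_),
    khansary  = cbind(1 / T_, P, P^2 / T_, log(rho), P * log(rho)),
    sodeifian = cbind(1, P^2 / T_, log(rho * T_), rho * log(rho),
                      P * log(T_), log(rho) / T_),
    belghait  = cbind(1, rho, rho^2, rho * T_, T_, T_^2, log(rho), 1 / T_)
  )
}

## Observed transformed response.
.se_observed <- function(spec, records, solute, solvent) {
  T_ <- records$temperature_K
  P <- records$pressure_MPa * .MPA_TO_BAR
  y <- records$mole_fraction
  switch(spec$model_id,
    chrastil = log(mole_fraction_to_mass_solubility(
      y, records$co2_density_kg_m3, solvent$molar_mass, solute$molar_mass)),
    mst = T_ * log(y * P),
    bartle = log(y * P / spec$reference_pressure),
    log(y)
  )
}

## Map the linear predictor eta to the model's native response.
.se_response_from_eta <- function(spec, eta, records) {
  T_ <- records$temperature_K
  P <- records$pressure_MPa * .MPA_TO_BAR
  switch(spec$model_id,
    chrastil = exp(eta),                       # S in kg m^-3
    mst = exp(eta / T_) / P,                   # y
    bartle = exp(eta) * spec$reference_pressure / P,  # y
    exp(eta)                                   # y
  )
}

#' Evaluate a semi-empirical model
#'
#' Closed-form evaluation of a model at given parameters for each record.
#' Returns the model's native response: mass solubility in kg m^-3 for the
#' Chrastil model, mole fraction for all others.
#'
#' @param spec an `se_model_spec` (or model id).
#' @param parameters numeric vector of length `spec$n_params` (a0, a1, ...).
#' @param records data.frame with `temperature_K`, `pressure_MPa`,
#'   `co2_density_kg_m3` (an `sc_dataset`'s `records`, or any grid).
#' @return numeric vector of predicted responses.
#' @export
evaluate_model <- function(spec, parameters, records) {
  if (is.character(spec)) spec <- se_model_spec(spec)
  stopifnot(inherits(spec, "se_model_spec"))
  if (length(parameters) != spec$n_params) {
    stop_scsolub("usage_error",
                 sprintf("model '%s' needs %d parameters, got %d",
                         spec$model_id, spec$n_params, length(parameters)))
  }
  X <- .se_design(spec, records)
  out <- .se_response_from_eta(spec, drop(X %*% parameters), records)
  if (any(!is.finite(out))) {
    stop_scsolub("evaluation_error",
                 "model evaluation produced a non-finite response")
  }
  out
}

#' Predicted mole fraction under a semi-empirical model
#'
#' Like [evaluate_model()] but always in mole-fraction space: the Chrastil
#' mass-solubility prediction is converted through the sampling-loop relation
#' with each record's density.
#'
#' @inheritParams evaluate_model
#' @param solute,solvent property cards (needed for the Chrastil conversion).
#' @export
predict_mole_fraction <- function(spec, parameters, records, solute, solvent) {
  if (is.character(spec)) spec <- se_model_spec(spec)
  resp <- evaluate_model(spec, parameters, records)
  if (spec$response == "mass_solubility_kg_m3") {
    n2 <- resp / solute$molar_mass
    n1 <- records$co2_density_kg_m3 / solvent$molar_mass
    n2 / (n1 + n2)
  } else {
    resp
  }
}

#' Average absolute relative deviation, percent
#'
#' \eqn{AARD\% = (100/N) \sum_i |y^{exp}_i - y^{cal}_i| / y^{exp}_i}.
#'
#' @param y_exp experimental values (strictly positive).
#' @param y_cal calculated values.
#' @export
aard <- function(y_exp, y_cal) {
  if (length(y_exp) != length(y_cal)) {
    stop_scsolub("usage_error", "y_exp and y_cal must have equal length")
  }
  if (any(y_exp <= 0)) {
    stop_scsolub("usage_error", "y_exp must be strictly positive")
  }
  mean(abs(y_exp - y_cal) / y_exp) * 100
}

#' Fit a semi-empirical model by AARD minimisation
#'
#' Minimises the average absolute relative deviation between experimental and
#' predicted mole fractions.  Residuals are always computed in mole-fraction
#' space (Chrastil predictions are converted through the loop relation), so
#' all ten models are compared on the same objective.
#'
#' The optimiser is deterministic for a given seed: an ordinary-least-squares
#' fit of the transformed linear form provides the initial point, Nelder-Mead
#' is restarted `n_restarts` times from perturbations of the incumbent (the
#' AARD objective is piecewise smooth, so a derivative-free polish is run
#' first), and a BFGS step finishes the incumbent if it improves.
#'
#' @param model one of [se_model_ids()] or an `se_model_spec`.
#' @param dataset an `sc_dataset`.
#' @param n_restarts number of perturbed restarts (default 64).
#' @param seed RNG seed for the restarts (default 20230207).
#' @param start optional user-supplied starting vector; the reported optimum
#'   is never worse than the objective polished from this start.
#' @return object of class `se_fit`: `spec`, `parameters` (named a0...),
#'   `aard_percent`, `residuals` (signed relative deviations),
#'   `predicted_y`, `optimizer_report`.
#' @export
fit_model <- function(model, dataset, n_restarts = 64L, seed = 20230207L,
                      start = NULL) {
  spec <- if (is.character(model)) se_model_spec(model) else model
  stopifnot(inherits(spec, "se_model_spec"), inherits(dataset, "sc_dataset"))
  records <- dataset$records
  if (nrow(records) < spec$n_params + 1L) {
    stop_scsolub("fit_error",
                 sprintf("need at least %d records to fit '%s'",
                         spec$n_params + 1L, spec$model_id))
  }
  y_exp <- records$mole_fraction
  X <- .se_design(spec, records)

  predict_y <- function(b) {
    eta <- drop(X %*% b)
    resp <- .se_response_from_eta(spec, eta, records)
    if (spec$response == "mass_solubility_kg_m3") {
      n2 <- resp / dataset$solute$molar_mass
      n1 <- records$co2_density_kg_m3 / dataset$solvent$molar_mass
      resp <- n2 / (n1 + n2)
    }
    resp
  }
  objective <- function(b) {
    y_cal <- predict_y(b)
    if (any(!is.finite(y_cal)) || any(y_cal <= 0)) return(1e8)
    v <- aard(y_exp, y_cal)
    if (!is.finite(v)) 1e8 else v  # AARD itself can overflow for wild starts
  }

  nm <- function(b) {
    o <- stats::optim(b, objective, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    stats::optim(o$par, objective, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
  }

  z <- .se_observed(spec, records, dataset$solute, dataset$solvent)
  b_ols <- tryCatch(qr.solve(X, z), error = function(e)
    stop_scsolub("fit_error", "singular design matrix; check the data grid"))
  best <- nm(b_ols)
  n_eval <- best$counts[["function"]]
  if (!is.null(start)) {
    if (length(start) != spec$n_params) {
      stop_scsolub("usage_error", "start has the wrong length")
    }
    cand <- nm(start)
    n_eval <- n_eval + cand$counts[["function"]]
    if (cand$value < best$value) best <- cand
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  scale0 <- pmax(abs(best$par), 1e-3)
  for (i in seq_len(n_restarts)) {
    st <- best$par * (1 + stats::rnorm(spec$n_params, 0, 0.2)) +
      stats::rnorm(spec$n_params, 0, 0.02 * scale0)
    cand <- nm(st)
    n_eval <- n_eval + cand$counts[["function"]]
    if (cand$value < best$value) best <- cand
  }
  polish <- tryCatch(
    stats::optim(best$par, objective, method = "BFGS",
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$value) && polish$value < best$value) {
    best <- polish
  }
  final <- nm(best$par)
  if (final$value < best$value) best <- final
  n_eval <- n_eval + final$counts[["function"]]

  y_cal <- predict_y(best$par)
  params <- stats::setNames(best$par, paste0("a", seq_len(spec$n_params) - 1L))
  structure(list(
    spec = spec, parameters = params,
    aard_percent = best$value,
    residuals = (y_cal - y_exp) / y_exp,
    predicted_y = y_cal,
    optimizer_report = list(seed = seed, restarts = n_restarts,
                            function_evaluations = n_eval,
                            converged = best$convergence == 0L),
    n_records = nrow(records)
  ), class = "se_fit")
}

#' @export
print.se_fit <- function(x, ...) {
  cat(sprintf("<se_fit> %s: AARD = %.2f%% over %d records\n",
              x$spec$model_id, x$aard_percent, x$n_records))
  cat("  parameters:", paste(sprintf("%s = %.6g", names(x$parameters),
                                     x$parameters), collapse = ", "), "\n")
  invisible(x)
}

#' Dissolution, vaporization and solvation enthalpies
#'
#' The total dissolution enthalpy is minus the Chrastil temperature
#' coefficient times the gas constant; the vaporization enthalpy is minus the
#' Bartle temperature coefficient times the gas constant; the solvation
#' enthalpy is their difference:
#' \deqn{\Delta H_{total} = -a_1^{Chrastil} R,\quad
#'       \Delta H_{vap} = -a_2^{Bartle} R,\quad
#'       \Delta H_{sol} = \Delta H_{total} - \Delta H_{vap}.}
#'
#' @param chrastil_fit an `se_fit` of the Chrastil model.
#' @param bartle_fit an `se_fit` of the Bartle model.
#' @param gas_constant J mol^-1 K^-1 (default [RGAS]).
#' @return object of class `enthalpy_estimates` with `total`, `vaporization`,
#'   `solvation` (kJ mol^-1), `gas_constant_used` and fit provenance.
#' @export
enthalpies <- function(chrastil_fit, bartle_fit, gas_constant = RGAS) {
  if (!inherits(chrastil_fit, "se_fit") ||
      chrastil_fit$spec$model_id != "chrastil") {
    stop_scsolub("usage_error", "chrastil_fit must be a Chrastil se_fit")
  }
  if (!inherits(bartle_fit, "se_fit") || bartle_fit$spec$model_id != "bartle") {
    stop_scsolub("usage_error", "bartle_fit must be a Bartle se_fit")
  }
  total <- -chrastil_fit$parameters[["a1"]] * gas_constant / 1000
  vap <- -bartle_fit$parameters[["a2"]] * gas_constant / 1000
  structure(list(
    total = total, vaporization = vap, solvation = total - vap,
    gas_constant_used = gas_constant,
    provenance = list(chrastil_aard = chrastil_fit$aard_percent,
                      bartle_aard = bartle_fit$aard_percent)
  ), class = "enthalpy_estimates")
}

#' @export
print.enthalpy_estimates <- function(x, ...) {
  cat(sprintf(paste0("<enthalpy_estimates> total %.2f, vaporization %.2f, ",
                     "solvation %.2f kJ/mol\n"),
              x$total, x$vaporization, x$solvation))
  invisible(x)
}

#' Linear-collapse self-consistency test
#'
#' Transforms the data with a fitted model's temperature coefficient so that,
#' if the data are internally consistent with the model family, all isotherms
#' collapse onto one straight line:
#' Chrastil coordinates \eqn{(\ln\rho,\ \ln S - a_1/T)}; MST coordinates
#' \eqn{(\rho,\ T\ln(yP) - a_2 T)} with P in bar.  A single least-squares
#' line is fitted across all temperatures and its R^2 reported.
#'
#' @param model_id `"chrastil"` or `"mst"`.
#' @param fit the corresponding `se_fit` on the same dataset.
#' @param dataset an `sc_dataset`.
#' @return object of class `consistency_result` with `abscissa`, `ordinate`,
#'   `slope`, `intercept`, `r_squared`.
#' @export
consistency_test <- function(model_id = c("chrastil", "mst"), fit, dataset) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(fit, "se_fit"), inherits(dataset, "sc_dataset"))
  if (fit$spec$model_id != model_id) {
    stop_scsolub("usage_error", "fit does not match model_id")
  }
  r <- dataset$records
  T_ <- r$temperature_K
  P <- r$pressure_MPa * .MPA_TO_BAR
  if (model_id == "chrastil") {
    S <- mole_fraction_to_mass_solubility(
      r$mole_fraction, r$co2_density_kg_m3,
      dataset$solvent$molar_mass, dataset$solute$molar_mass)
    x <- log(r$co2_density_kg_m3)
    yy <- log(S) - fit$parameters[["a1"]] / T_
  } else {
    x <- r$co2_density_kg_m3
    yy <- T_ * log(r$mole_fraction * P) - fit$parameters[["a2"]] * T_
  }
  lmfit <- stats::lm(yy ~ x)
  ss_res <- sum(stats::residuals(lmfit)^2)
  ss_tot <- sum((yy - mean(yy))^2)
  structure(list(
    model_id = model_id, abscissa = x, ordinate = yy,
    slope = unname(stats::coef(lmfit)[2]),
    intercept = unname(stats::coef(lmfit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  ), class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("<consistency_result> %s collapse: R^2 = %.4f (slope %.4g)\n",
              x$model_id, x$r_squared, x$slope))
  invisible(x)
}

#' Density interpolator from a dataset's isotherms
#'
#' Builds rho(T, P) for the dataset's grid temperatures by monotone spline
#' interpolation of each isotherm's (P, rho) points.
#'
#' @param dataset an `sc_dataset`.
#' @return function(T, P) returning kg m^-3 (T must be a grid temperature).
#' @export
density_interpolator <- function(dataset) {
  r <- dataset$records
  temps <- sort(unique(r$temperature_K))
  funs <- lapply(temps, function(tt) {
    i <- r$temperature_K == tt
    stats::splinefun(r$pressure_MPa[i], r$co2_density_kg_m3[i], method = "hyman")
  })
  names(funs) <- as.character(temps)
  function(T, P) {
    f <- funs[[as.character(T)]]
    if (is.null(f)) {
      stop_scsolub("usage_error",
                   sprintf("no isotherm at T = %g K in the dataset", T))
    }
    f(P)
  }
}

#' Locate the crossover pressure of two fitted isotherms
#'
#' Finds the pressure where the fitted model predicts equal mole fractions at
#' two temperatures (below it solubility falls with temperature, above it
#' rises).  Densities along each isotherm come from `density_fun`
#' (default: interpolated from the dataset).
#'
#' @param fit an `se_fit`.
#' @param dataset the fitted `sc_dataset`.
#' @param T1,T2 two grid temperatures, K.
#' @param interval pressure search interval in MPa (default the data range).
#' @param density_fun optional function(T, P) -> kg m^-3.
#' @return crossover pressure in MPa, or NA if the isotherms do not cross in
#'   the interval.
#' @export
crossover_pressure <- function(fit, dataset, T1, T2, interval = NULL,
                               density_fun = NULL) {
  stopifnot(inherits(fit, "se_fit"), inherits(dataset, "sc_dataset"))
  if (is.null(density_fun)) density_fun <- density_interpolator(dataset)
  if (is.null(interval)) interval <- range(dataset$records$pressure_MPa)
  gap <- function(P) {
    rec <- function(T) data.frame(temperature_K = T, pressure_MPa = P,
                                  co2_density_kg_m3 = density_fun(T, P))
    y1 <- predict_mole_fraction(fit$spec, fit$parameters, rec(T1),
                                dataset$solute, dataset$solvent)
    y2 <- predict_mole_fraction(fit$spec, fit$parameters, rec(T2),
                                dataset$solute, dataset$solvent)
    log(y1) - log(y2)
  }
  lo <- gap(interval[1]); hi <- gap(interval[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) return(NA_real_)
  stats::uniroot(gap, interval, tol = 1e-6)$root
}
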