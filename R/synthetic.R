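## Synthetic solubility datasets with the statistical and physical structure
## of the packaged study: an isothermal T x P grid, densities from either the
## packaged study table or the pure-CO2 PR equation, true mole fractions from
## a chosen truth model, and triplicate multiplicative (lognormal)
## measurement noise.

#' Synthetic-dataset specification
#'
#' @param truth semi-empirical truth: a list `list(model, parameters)` (model
#'   id or `se_model_spec`), an `se_fit`, or an EoS truth given as a
#'   [mixing_rule()].
#' @param temperature_grid K (default the study grid 308-338 K).
#' @param pressure_grid MPa (default 12-27 MPa).
#' @param density_source `"packaged_table2"` (interpolated from the packaged
#'   study's NIST densities) or `"pure_pr_co2"` (pure-CO2 PR density).
#' @param noise_sigma relative lognormal noise scale (>= 0; default 0.03,
#'   the replicate scatter level of the packaged study).
#' @param replicates runs per condition (>= 1; default 3).
#' @param seed RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(truth,
                           temperature_grid = c(308, 318, 328, 338),
                           pressure_grid = c(12, 15, 18, 21, 24, 27),
                           density_source = c("packaged_table2", "pure_pr_co2"),
                           noise_sigma = 0.03, replicates = 3L, seed = 1L) {
  density_source <- match.arg(density_source)
  if (!length(temperature_grid) || !length(pressure_grid)) {
    stop_scsolub("usage_error", "temperature and pressure grids must be non-empty")
  }
  if (noise_sigma < 0) stop_scsolub("usage_error", "noise_sigma must be >= 0")
  if (replicates < 1L) stop_scsolub("usage_error", "replicates must be >= 1")
  if (inherits(truth, "se_fit")) {
    truth <- list(model = truth$spec, parameters = truth$parameters)
  }
  if (!inherits(truth, "mixing_rule")) {
    if (!is.list(truth) || is.null(truth$model) || is.null(truth$parameters)) {
      stop_scsolub("usage_error",
                   "truth must be list(model, parameters), an se_fit or a mixing_rule")
    }
    if (is.character(truth$model)) truth$model <- se_model_spec(truth$model)
  }
  structure(list(truth = truth, temperature_grid = sort(temperature_grid),
                 pressure_grid = sort(pressure_grid),
                 density_source = density_source, noise_sigma = noise_sigma,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Pure-CO2 density from the PR equation
#'
#' @param solvent a [solvent_card()].
#' @param temperature K.
#' @param pressure MPa.
#' @return density in kg m^-3 (stable root).
#' @export
pr_co2_density <- function(solvent, temperature, pressure) {
  p <- pure_pr_params(solvent, temperature)
  A <- p$attraction * pressure * 1e6 / (RGAS * temperature)^2
  B <- p$covolume * pressure * 1e6 / (RGAS * temperature)
  Z <- .pr_pick_root(A, B)
  if (is.na(Z)) {
    stop_scsolub("thermodynamic_state_error", "no PR root for pure CO2")
  }
  V <- Z * RGAS * temperature / (pressure * 1e6)
  solvent$molar_mass * 1e-3 / V
}

#' Generate a synthetic solubility dataset
#'
#' Builds the full grid, evaluates the truth model, adds multiplicative
#' lognormal replicate noise \eqn{y\,e^{\epsilon}},
#' \eqn{\epsilon \sim N(0, \sigma^2)}, and reduces replicates to records
#' carrying the replicate mean, sample standard deviation and expanded
#' uncertainty (k = 2 on the standard uncertainty of the mean).  Deterministic
#' for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @param solute,solvent property cards (default: the packaged study's).
#' @return an `sc_dataset`; the replicate-level table is attached as
#'   `attr(, "replicates")`.
#' @export
generate_dataset <- function(spec, solute = NULL, solvent = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(solute) || is.null(solvent)) {
    study <- builtin_palbociclib_study()
    if (is.null(solute)) solute <- study$solute
    if (is.null(solvent)) solvent <- study$solvent
  }
  grid <- expand.grid(pressure_MPa = spec$pressure_grid,
                      temperature_K = spec$temperature_grid)[, 2:1]

  rho <- if (spec$density_source == "packaged_table2") {
    dint <- density_interpolator(builtin_palbociclib_study())
    mapply(dint, grid$temperature_K, grid$pressure_MPa)
  } else {
    mapply(function(T, P) pr_co2_density(solvent, T, P),
           grid$temperature_K, grid$pressure_MPa)
  }
  grid$co2_density_kg_m3 <- rho

  y_true <- if (inherits(spec$truth, "mixing_rule")) {
    vapply(seq_len(nrow(grid)), function(i) {
      solve_solubility(solute, solvent, grid$temperature_K[i],
                       grid$pressure_MPa[i], spec$truth)$mole_fraction
    }, 0)
  } else {
    predict_mole_fraction(spec$truth$model, spec$truth$parameters, grid,
                          solute, solvent)
  }
  if (any(!is.finite(y_true)) || any(y_true <= 0)) {
    stop_scsolub("evaluation_error", "truth model produced non-positive y")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  n <- spec$replicates
  reps <- lapply(seq_len(nrow(grid)), function(i) {
    y_true[i] * exp(stats::rnorm(n, 0, spec$noise_sigma))
  })
  mean_y <- vapply(reps, mean, 0)
  std_y <- if (n >= 2L) vapply(reps, stats::sd, 0) else rep(NA_real_, nrow(grid))
  U <- if (n >= 2L) 2 * std_y / sqrt(n) else rep(NA_real_, nrow(grid))

  records <- data.frame(
    temperature_K = grid$temperature_K, pressure_MPa = grid$pressure_MPa,
    co2_density_kg_m3 = grid$co2_density_kg_m3,
    mole_fraction = mean_y,
    mass_solubility_g_L = mole_fraction_to_mass_solubility(
      mean_y, grid$co2_density_kg_m3, solvent$molar_mass, solute$molar_mass),
    std_y = std_y, expanded_uncertainty_y = U
  )
  ds <- solubility_dataset(records, solute, solvent,
                           provenance = sprintf(
                             "synthetic (%s truth, sigma = %g, %d replicates, seed %d)",
                             if (inherits(spec$truth, "mixing_rule")) spec$truth$kind
                             else spec$truth$model$model_id,
                             spec$noise_sigma, n, spec$seed))
  rep_table <- data.frame(
    temperature_K = rep(grid$temperature_K, each = n),
    pressure_MPa = rep(grid$pressure_MPa, each = n),
    replicate = rep(seq_len(n), nrow(grid)),
    mole_fraction = unlist(reps)
  )
  attr(ds, "replicates") <- rep_table
  attr(ds, "true_y") <- y_true
  ds
}
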