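#' Reduce a trapped-solvent sample to solubility and mole fraction
#'
#' Converts one sampling-loop measurement to equilibrium mass solubility and
#' mole fraction.  The saturated supercritical phase in the loop (volume
#' `loop_volume`) is flushed into a trapping-solvent vial (final solution
#' volume `solution_volume`) and the solute concentration `C2` of that
#' solution is measured spectrophotometrically.  Then
#' \deqn{S_2 = C_2 V_s / V_l, \qquad y_2 = n_2/(n_1+n_2)}
#' with \eqn{n_1 = \rho_1 V_l / M_1} the moles of solvent that occupied the
#' loop and \eqn{n_2 = C_2 V_s / M_2} the moles of solute recovered.
#'
#' @param solute_concentration C2, concentration of solute in the trapping
#'   solution, g L^-1 (>= 0).
#' @param loop_volume V_l, sampling-loop volume, L.
#' @param solution_volume V_s, trapping-solution volume, L.
#' @param co2_density rho_1, solvent density in the loop, kg m^-3.
#' @param solvent_molar_mass M1, g mol^-1.
#' @param solute_molar_mass M2, g mol^-1.
#' @return list with `mass_solubility` (g L^-1) and `mole_fraction`.
#' @examples
#' reduce_sample(0.0305 / (600e-6 / 0.005), loop_volume = 600e-6,
#'               solution_volume = 0.005, co2_density = 769,
#'               solvent_molar_mass = 44.01, solute_molar_mass = 447.54)
#' @export
reduce_sample <- function(solute_concentration, loop_volume, solution_volume,
                          co2_density, solvent_molar_mass, solute_molar_mass) {
  if (!is.numeric(solute_concentration) || any(solute_concentration < 0)) {
    stop_scsolub("domain_error", "solute_concentration must be >= 0")
  }
  for (v in list(loop_volume = loop_volume, solution_volume = solution_volume,
                 co2_density = co2_density,
                 solvent_molar_mass = solvent_molar_mass,
                 solute_molar_mass = solute_molar_mass)) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop_scsolub("domain_error",
                   "volumes, density and molar masses must be > 0")
    }
  }
  S2 <- solute_concentration * solution_volume / loop_volume
  n1 <- co2_density * loop_volume / solvent_molar_mass
  n2 <- solute_concentration * solution_volume / solute_molar_mass
  y2 <- n2 / (n1 + n2)
  list(mass_solubility = S2, mole_fraction = y2)
}

#' Invert the sample reduction
#'
#' Recovers the trapping-solution concentration C2 that would reproduce a
#' given mole fraction; `reduce_sample()` composed with this map is the
#' identity.
#'
#' @inheritParams reduce_sample
#' @param mole_fraction equilibrium solute mole fraction.
#' @return C2 in g L^-1.
#' @export
invert_reduction <- function(mole_fraction, loop_volume, solution_volume,
                             co2_density, solvent_molar_mass, solute_molar_mass) {
  n1 <- co2_density * loop_volume / solvent_molar_mass
  n2 <- mole_fraction / (1 - mole_fraction) * n1
  n2 * solute_molar_mass / solution_volume
}

#' Replicate statistics with expanded uncertainty
#'
#' Computes the replicate mean, the sample standard deviation
#' \eqn{\sqrt{\sum_j (y_j-\bar y)^2/(n-1)}} and the expanded uncertainty
#' \eqn{U(\bar y) = k\, u_{comb}} with the relative combined standard
#' uncertainty \eqn{u_{comb}/\bar y =
#' \sqrt{\sum_i (P_i u_i(x_i)/x_i)^2}} built from user-supplied relative
#' contributions (sensitivity-weighted relative standard uncertainties of the
#' input quantities).
#'
#' @param mole_fractions replicate mole fractions (n >= 2).
#' @param relative_components vector of relative uncertainty contributions
#'   P_i u_i(x_i)/x_i; the replicate scatter itself can be passed as one of
#'   them.
#' @param coverage_factor k (default 2, approximately 95 % confidence).
#' @return list with `mean_y`, `std_y`, `u_comb`, `expanded_uncertainty`.
#' @export
replicate_statistics <- function(mole_fractions, relative_components = numeric(),
                                 coverage_factor = 2) {
  if (length(mole_fractions) < 2L) {
    stop_scsolub("insufficient_replicates",
                 "at least 2 replicates are needed for a standard deviation")
  }
  .chk_num(coverage_factor, "coverage_factor", positive = TRUE)
  m <- mean(mole_fractions)
  s <- stats::sd(mole_fractions)
  u_rel <- sqrt(sum(relative_components^2))
  u_comb <- u_rel * m
  list(mean_y = m, std_y = s, u_comb = u_comb,
       expanded_uncertainty = coverage_factor * u_comb)
}

#' Reduce a table of raw samples
#'
#' Applies [reduce_sample()] to each row of a raw-sample table (columns
#' `C2_g_L, loop_volume_L, solution_volume_L, co2_density_kg_m3`).
#'
#' @param raw data.frame or path to a CSV file with the columns above.
#' @param solvent_molar_mass,solute_molar_mass g mol^-1.
#' @return data.frame with `mass_solubility_g_L` and `mole_fraction` appended.
#' @export
reduce_samples <- function(raw, solvent_molar_mass, solute_molar_mass) {
  if (is.character(raw)) raw <- utils::read.csv(raw, stringsAsFactors = FALSE)
  need <- c("C2_g_L", "loop_volume_L", "solution_volume_L", "co2_density_kg_m3")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_scsolub("schema_error",
                 sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  red <- reduce_sample(raw$C2_g_L, raw$loop_volume_L, raw$solution_volume_L,
                       raw$co2_density_kg_m3, solvent_molar_mass,
                       solute_molar_mass)
  raw$mass_solubility_g_L <- red$mass_solubility
  raw$mole_fraction <- red$mole_fraction
  raw
}
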