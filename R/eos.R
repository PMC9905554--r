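## Peng-Robinson equation of state: pure-component parameters, mixture
## fugacity coefficients under van der Waals / Wong-Sandler / Huron-Vidal
## mixing rules, solid-fluid equifugacity, and binary-parameter regression.
##
## Unit conventions: exported functions take T in K and P in MPa (the storage
## units); internally everything is SI (Pa, m^3, J).  a is in Pa m^6 mol^-2,
## b and volumes in m^3 mol^-1, fugacities in Pa.

.C_WS <- log(sqrt(2) - 1) / sqrt(2)  # Wong-Sandler EoS/Gibbs coupling constant
.C_HV <- log(2)                      # Huron-Vidal coupling constant

#' Pure-component Peng-Robinson parameters
#'
#' Standard 1976 construction from the critical constants and acentric
#' factor: \eqn{b = 0.07780 R T_c / P_c},
#' \eqn{a(T) = 0.45724 R^2 T_c^2 / P_c \, \alpha(T)} with
#' \eqn{\alpha = (1 + \kappa(1 - \sqrt{T/T_c}))^2} and
#' \eqn{\kappa = 0.37464 + 1.54226\omega - 0.26992\omega^2}.
#'
#' @param card a `solute_card` or `solvent_card` (critical temperature K,
#'   critical pressure MPa, acentric factor).
#' @param temperature K.
#' @return list with `attraction` (a, Pa m^6 mol^-2), `covolume`
#'   (b, m^3 mol^-1) and `alpha`.
#' @export
pure_pr_params <- function(card, temperature) {
  .chk_num(temperature, "temperature", positive = TRUE)
  Tc <- card$critical_temperature
  Pc <- card$critical_pressure * 1e6
  w <- card$acentric_factor
  if (!is.finite(Tc) || Tc <= 0 || !is.finite(Pc) || Pc <= 0) {
    stop_scsolub("domain_error", "critical constants must be positive")
  }
  kappa <- 0.37464 + 1.54226 * w - 0.26992 * w^2
  alpha <- (1 + kappa * (1 - sqrt(temperature / Tc)))^2
  list(attraction = 0.45724 * RGAS^2 * Tc^2 / Pc * alpha,
       covolume = 0.07780 * RGAS * Tc / Pc,
       alpha = alpha)
}

## Real roots Z > B of the PR compressibility cubic
## Z^3 - (1-B) Z^2 + (A - 3B^2 - 2B) Z - (AB - B^2 - B^3) = 0.
.pr_zroots <- function(A, B) {
  if (!all(is.finite(c(A, B)))) return(numeric())
  r <- polyroot(c(-(A * B - B^2 - B^3), A - 3 * B^2 - 2 * B, -(1 - B), 1))
  z <- Re(r[abs(Im(r)) < 1e-8 * pmax(1, Mod(r))])
  sort(z[z > B])
}

## Residual molar Gibbs energy / RT at given root.
.pr_gres <- function(Z, A, B) {
  Z - 1 - log(Z - B) -
    A / (2 * sqrt(2) * B) * log((Z + (1 + sqrt(2)) * B) / (Z + (1 - sqrt(2)) * B))
}

## Root with the lowest residual Gibbs energy (stable phase).
.pr_pick_root <- function(A, B) {
  z <- .pr_zroots(A, B)
  if (!length(z)) return(NA_real_)
  if (length(z) == 1L) return(z)
  z[which.min(vapply(z, .pr_gres, 0, A = A, B = B))]
}

#' Molar-volume roots of the Peng-Robinson equation
#'
#' Solves \eqn{P = RT/(V-b) - a/(V(V+b)+b(V-b))} for V at given T, P and
#' mixture parameters.  When three real roots exist the smallest is labelled
#' liquid-like and the largest vapor-like.
#'
#' @param temperature K.
#' @param pressure MPa.
#' @param a mixture attraction, Pa m^6 mol^-2.
#' @param b mixture covolume, m^3 mol^-1.
#' @return data.frame with `volume` (m^3 mol^-1), `Z`, and `label`
#'   (liquid/vapor/middle).
#' @export
solve_volume <- function(temperature, pressure, a, b) {
  .chk_num(pressure, "pressure", positive = TRUE)
  P <- pressure * 1e6
  A <- a * P / (RGAS * temperature)^2
  B <- b * P / (RGAS * temperature)
  z <- .pr_zroots(A, B)
  if (!length(z)) {
    stop_scsolub("thermodynamic_state_error",
                 "no molar-volume root above the covolume at this state")
  }
  lab <- if (length(z) == 1L) "fluid" else
    c("liquid", if (length(z) == 3L) "middle", "vapor")
  data.frame(volume = z * RGAS * temperature / P, Z = z, label = lab)
}

#' Excess-Gibbs models for the Wong-Sandler / Huron-Vidal rules
#'
#' `ge_wilson()` implements the Wilson expression
#' \eqn{\bar G^E = -RT \sum_i x_i \ln(\sum_j x_j \Lambda_{ij})} with
#' \eqn{\Lambda_{ij} = \exp(-u_{ij}/RT)} (no molar-volume prefactor),
#' `ge_ideal()` the ideal solution (\eqn{\bar G^E = 0}), and `ge_custom()`
#' wraps any user function(T, x) returning J mol^-1.
#'
#' @param u12,u21 Wilson interaction energies, J mol^-1.
#' @return object of class `ge_model`.
#' @export
ge_wilson <- function(u12, u21) {
  .chk_num(u12, "u12"); .chk_num(u21, "u21")
  structure(list(kind = "wilson", u12 = u12, u21 = u21,
                 fun = function(T, x) {
                   L12 <- exp(-u12 / (RGAS * T))
                   L21 <- exp(-u21 / (RGAS * T))
                   -RGAS * T * (x[1] * log(x[1] + x[2] * L12) +
                                  x[2] * log(x[1] * L21 + x[2]))
                 }), class = "ge_model")
}

#' @rdname ge_wilson
#' @export
ge_ideal <- function() {
  structure(list(kind = "ideal", fun = function(T, x) 0), class = "ge_model")
}

#' @rdname ge_wilson
#' @param fun function(T, x) -> excess Gibbs energy in J mol^-1.
#' @export
ge_custom <- function(fun) {
  stopifnot(is.function(fun))
  structure(list(kind = "custom", fun = fun), class = "ge_model")
}

#' Mixing-rule specification
#'
#' Builds the mixture-parameter prescription for the PR equation:
#' \describe{
#'   \item{vdw}{quadratic van der Waals rules with one binary interaction
#'     parameter: \eqn{a = \sum\sum x_i x_j \sqrt{a_i a_j}(1-k_{ij})},
#'     \eqn{b = \sum x_i b_i}.}
#'   \item{wong_sandler}{\eqn{a/b = \sum x_i a_i/b_i + \bar G^E/C_{WS}} with
#'     the second-virial covolume constraint and
#'     \eqn{C_{WS} = \ln(\sqrt2 - 1)/\sqrt2}; needs a `ge_model`.}
#'   \item{huron_vidal}{\eqn{a/b = \sum x_i a_i/b_i + \bar G^E/C_{HV}},
#'     \eqn{b = \sum x_i b_i}, \eqn{C_{HV} = \ln 2}; needs a `ge_model`.}
#' }
#'
#' @param kind one of `"vdw"`, `"wong_sandler"`, `"huron_vidal"`.
#' @param k12 binary interaction parameter (vdw only).
#' @param ge_model a [ge_wilson()], [ge_ideal()] or [ge_custom()] (WS/HV).
#' @return object of class `mixing_rule`.
#' @export
mixing_rule <- function(kind = c("vdw", "wong_sandler", "huron_vidal"),
                        k12 = NULL, ge_model = NULL) {
  kind <- match.arg(kind)
  if (kind == "vdw") {
    if (is.null(k12) || !is.null(ge_model)) {
      stop_scsolub("usage_error", "vdW mixing rule takes exactly one k12")
    }
    .chk_num(k12, "k12")
  } else {
    if (is.null(ge_model) || !inherits(ge_model, "ge_model") || !is.null(k12)) {
      stop_scsolub("usage_error",
                   sprintf("%s mixing rule needs a ge_model (and no k12)", kind))
    }
  }
  structure(list(kind = kind, k12 = k12, ge_model = ge_model,
                 C = switch(kind, vdw = NA_real_, wong_sandler = .C_WS,
                            huron_vidal = .C_HV)),
            class = "mixing_rule")
}

#' @export
print.mixing_rule <- function(x, ...) {
  if (x$kind == "vdw") {
    cat(sprintf("<mixing_rule> vdW, k12 = %.5g\n", x$k12))
  } else {
    par <- if (!is.null(x$ge_model$u12))
      sprintf(", u12 = %.5g, u21 = %.5g J/mol", x$ge_model$u12, x$ge_model$u21)
    else ""
    cat(sprintf("<mixing_rule> %s + %s GE%s\n", x$kind, x$ge_model$kind, par))
  }
  invisible(x)
}

## Mixture a, b for any rule.  p1/p2: pure_pr_params lists. x: length-2.
.mix_ab <- function(rule, T, x, p1, p2) {
  ai <- c(p1$attraction, p2$attraction)
  bi <- c(p1$covolume, p2$covolume)
  if (rule$kind == "vdw") {
    a12 <- sqrt(ai[1] * ai[2]) * (1 - rule$k12)
    a <- x[1]^2 * ai[1] + 2 * x[1] * x[2] * a12 + x[2]^2 * ai[2]
    return(list(a = a, b = sum(x * bi)))
  }
  GE <- rule$ge_model$fun(T, x)
  if (!is.finite(GE)) return(list(a = NA_real_, b = NA_real_))
  aob <- sum(x * ai / bi) + GE / rule$C
  if (rule$kind == "huron_vidal") {
    b <- sum(x * bi)
    return(list(a = b * aob, b = b))
  }
  ## Wong-Sandler: b from the second-virial combination; both the numerator
  ## and (1 - D) are negative at supercritical CO2 conditions and cancel.
  Qij <- outer(bi, bi, "+") / 2 - sqrt(outer(ai, ai)) / (RGAS * T)
  Q <- drop(t(x) %*% Qij %*% x)
  D <- sum(x * ai / (bi * RGAS * T)) + GE / (rule$C * RGAS * T)
  b <- Q / (1 - D)
  if (!is.finite(b) || b <= 0) return(list(a = NA_real_, b = NA_real_))
  list(a = b * aob, b = b)
}

## Residual molar Gibbs/RT of the mixture at (T, P, x) under `rule`.
.mix_gres <- function(rule, T, P, x, p1, p2) {
  m <- .mix_ab(rule, T, x, p1, p2)
  if (!is.finite(m$a) || !is.finite(m$b) || m$b <= 0) return(NA_real_)
  A <- m$a * P / (RGAS * T)^2
  B <- m$b * P / (RGAS * T)
  Z <- .pr_pick_root(A, B)
  if (is.na(Z)) return(NA_real_)
  .pr_gres(Z, A, B)
}

## Closed-form PR fugacity coefficients under vdW rules.
.lnphi_vdw <- function(T, P, x, p1, p2, k12) {
  ai <- c(p1$attraction, p2$attraction)
  bi <- c(p1$covolume, p2$covolume)
  a12 <- sqrt(ai[1] * ai[2]) * (1 - k12)
  am <- x[1]^2 * ai[1] + 2 * x[1] * x[2] * a12 + x[2]^2 * ai[2]
  bm <- sum(x * bi)
  A <- am * P / (RGAS * T)^2
  B <- bm * P / (RGAS * T)
  Z <- .pr_pick_root(A, B)
  if (is.na(Z)) return(c(NA_real_, NA_real_))
  sa <- c(x[1] * ai[1] + x[2] * a12, x[1] * a12 + x[2] * ai[2])
  bi / bm * (Z - 1) - log(Z - B) -
    A / (2 * sqrt(2) * B) * (2 * sa / am - bi / bm) *
    log((Z + (1 + sqrt(2)) * B) / (Z + (1 - sqrt(2)) * B))
}

## Numerically exact partial-derivative fugacity coefficients:
## ln phi_i = d(n g_res)/dn_i at constant T, P, by central differences with
## step 1e-6 n (capped at n_i/2 so mole numbers stay positive).
.lnphi_fd <- function(rule, T, P, x, p1, p2, which = 1:2, h = 1e-6) {
  Fn <- function(n) sum(n) * .mix_gres(rule, T, P, n / sum(n), p1, p2)
  vapply(which, function(i) {
    hi <- min(h, x[i] / 2)
    e <- c(0, 0); e[i] <- hi
    (Fn(x + e) - Fn(x - e)) / (2 * hi)
  }, 0)
}

#' Mixture fugacity coefficients
#'
#' Returns \eqn{\ln\varphi_i} of both components at (T, P, x) under the given
#' mixing rule.  For vdW rules the closed-form PR expression is used; for the
#' Wong-Sandler and Huron-Vidal rules the coefficients are numerically exact
#' partial derivatives of the total residual Gibbs energy (central
#' differences in mole numbers at constant T and P).
#'
#' @param temperature K.
#' @param pressure MPa.
#' @param composition length-2 mole-fraction vector (solvent, solute),
#'   summing to 1 within 1e-12.
#' @param rule a [mixing_rule()].
#' @param solvent,solute property cards.
#' @return numeric length-2 vector of ln phi (solvent, solute).
#' @export
fugacity_coefficients <- function(temperature, pressure, composition, rule,
                                  solvent, solute) {
  stopifnot(inherits(rule, "mixing_rule"))
  if (abs(sum(composition) - 1) > 1e-12) {
    stop_scsolub("usage_error", "composition must sum to 1")
  }
  P <- pressure * 1e6
  p1 <- pure_pr_params(solvent, temperature)
  p2 <- pure_pr_params(solute, temperature)
  out <- if (rule$kind == "vdw") {
    .lnphi_vdw(temperature, P, composition, p1, p2, rule$k12)
  } else {
    .lnphi_fd(rule, temperature, P, composition, p1, p2)
  }
  if (any(!is.finite(out))) {
    stop_scsolub("thermodynamic_state_error",
                 "fugacity-coefficient evaluation failed (no valid root)")
  }
  out
}

#' Subcooled-liquid reference state of the pure solute
#'
#' Liquid-like root of the pure-solute PR equation at (T, P): returns the
#' liquid molar volume and the (hypothetical subcooled) liquid fugacity
#' \eqn{f^L = \varphi^L P}.  When only one root exists it is used.
#'
#' @param card `solute_card`.
#' @param temperature K.
#' @param pressure MPa.
#' @return list with `fugacity` (Pa) and `molar_volume` (m^3 mol^-1).
#' @export
pure_liquid_reference <- function(card, temperature, pressure) {
  p <- pure_pr_params(card, temperature)
  P <- pressure * 1e6
  A <- p$attraction * P / (RGAS * temperature)^2
  B <- p$covolume * P / (RGAS * temperature)
  z <- .pr_zroots(A, B)
  if (!length(z)) {
    stop_scsolub("thermodynamic_state_error", "no PR root for the pure solute")
  }
  Z <- z[1]  # smallest root = liquid-like
  list(fugacity = exp(.pr_gres(Z, A, B)) * P,
       molar_volume = Z * RGAS * temperature / P)
}

#' Solid fugacity from the subcooled-liquid reference
#'
#' \deqn{\ln\frac{f^S}{f^L} = \frac{\Delta \bar H_m}{R T_m}
#'   \left(1 - \frac{T_m}{T}\right)
#'   + \frac{(\bar V^S - \bar V^L)(P - P_{atm})}{RT}}
#' with \eqn{P_{atm}} = 101,325 Pa.
#'
#' @param card `solute_card` (fusion enthalpy kJ mol^-1, melting point K,
#'   solid molar volume cm^3 mol^-1).
#' @param temperature K (must be below the melting point).
#' @param pressure MPa.
#' @param subcooled_liquid_fugacity f^L, Pa.
#' @param liquid_molar_volume m^3 mol^-1.
#' @return solid fugacity f^S in Pa.
#' @export
solid_fugacity <- function(card, temperature, pressure,
                           subcooled_liquid_fugacity, liquid_molar_volume) {
  if (temperature > card$melt_temperature) {
    stop_scsolub("domain_error",
                 "solid reference is only defined below the melting point")
  }
  P <- pressure * 1e6
  dHm <- card$fusion_enthalpy * 1000
  Tm <- card$melt_temperature
  Vs <- card$solid_molar_volume * 1e-6
  lnr <- dHm / (RGAS * Tm) * (1 - Tm / temperature) +
    (Vs - liquid_molar_volume) * (P - P_ATM) / (RGAS * temperature)
  subcooled_liquid_fugacity * exp(lnr)
}

## Internal fast equifugacity solver working on precomputed pure params and
## solid fugacity; returns y (or NA) and iteration count.
.solve_y <- function(rule, T, P, fs, p1, p2, y0 = 1e-5, tol = 1e-10,
                     max_iter = 200L, damping = 0.7) {
  yk <- y0
  for (i in seq_len(max_iter)) {
    lnphi2 <- if (rule$kind == "vdw") {
      .lnphi_vdw(T, P, c(1 - yk, yk), p1, p2, rule$k12)[2]
    } else {
      .lnphi_fd(rule, T, P, c(1 - yk, yk), p1, p2, which = 2)
    }
    if (!is.finite(lnphi2)) return(list(y = NA_real_, iterations = i, converged = FALSE))
    ynew <- fs / (exp(lnphi2) * P)
    if (!is.finite(ynew) || ynew <= 0) {
      return(list(y = NA_real_, iterations = i, converged = FALSE))
    }
    if (ynew >= 0.5) ynew <- 0.5
    step <- log(ynew) - log(yk)
    if (abs(step) < tol) {
      return(list(y = yk, iterations = i, converged = TRUE, lnphi2 = lnphi2))
    }
    yk <- exp(log(yk) + damping * step)
  }
  list(y = yk, iterations = max_iter, converged = FALSE)
}

#' Solve the solid-fluid equifugacity for the solute mole fraction
#'
#' Finds y2 such that \eqn{y_2 \varphi_2^{SC}(T,P,y) P = f^S(T,P)} by damped
#' successive substitution \eqn{y \leftarrow f^S / (\varphi_2^{SC} P)} from an
#' initial guess of 1e-5.
#'
#' @param solute,solvent property cards.
#' @param temperature K.
#' @param pressure MPa.
#' @param rule a fully parameterised [mixing_rule()].
#' @param y0 initial guess.
#' @param tol convergence tolerance on |delta ln y| (default 1e-10).
#' @param max_iter iteration cap (default 200).
#' @param damping step fraction in ln y (default 0.7).
#' @return object of class `equifugacity_result`: `mole_fraction`,
#'   `solid_fugacity`, `fluid_fugacity`, `subcooled_liquid_fugacity`,
#'   `liquid_molar_volume` (SI units), `iterations`, `converged`.
#' @export
solve_solubility <- function(solute, solvent, temperature, pressure, rule,
                             y0 = 1e-5, tol = 1e-10, max_iter = 200L,
                             damping = 0.7) {
  stopifnot(inherits(rule, "mixing_rule"))
  p1 <- pure_pr_params(solvent, temperature)
  p2 <- pure_pr_params(solute, temperature)
  ref <- pure_liquid_reference(solute, temperature, pressure)
  fs <- solid_fugacity(solute, temperature, pressure, ref$fugacity,
                       ref$molar_volume)
  P <- pressure * 1e6
  sol <- .solve_y(rule, temperature, P, fs, p1, p2, y0 = y0, tol = tol,
                  max_iter = max_iter, damping = damping)
  if (!sol$converged || is.na(sol$y)) {
    stop_scsolub("convergence_error",
                 sprintf("equifugacity iteration failed at T=%g K, P=%g MPa after %d iterations",
                         temperature, pressure, sol$iterations),
                 iterations = sol$iterations, last_y = sol$y)
  }
  structure(list(
    mole_fraction = sol$y,
    solid_fugacity = fs,
    fluid_fugacity = sol$y * exp(sol$lnphi2) * P,
    subcooled_liquid_fugacity = ref$fugacity,
    liquid_molar_volume = ref$molar_volume,
    iterations = sol$iterations, converged = sol$converged
  ), class = "equifugacity_result")
}

#' @export
print.equifugacity_result <- function(x, ...) {
  cat(sprintf("<equifugacity_result> y2 = %.4g (converged in %d iterations)\n",
              x$mole_fraction, x$iterations))
  invisible(x)
}

#' Average absolute deviation of log10 mole fraction
#'
#' \eqn{ALD\mbox{-}y = (1/N)\sum_i |\log_{10} y^{exp}_i - \log_{10} y^{cal}_i|};
#' the regression objective for the EoS binary parameters.
#'
#' @param y_exp,y_cal mole-fraction vectors.
#' @export
ald_y <- function(y_exp, y_cal) {
  if (length(y_exp) != length(y_cal)) {
    stop_scsolub("usage_error", "y_exp and y_cal must have equal length")
  }
  mean(abs(log10(y_exp) - log10(y_cal)))
}

#' Regress EoS binary interaction parameters against ALD-y
#'
#' Minimises ALD-y over the mixing rule's binary parameters: bounded scalar
#' search for the vdW k12 in [-0.5, 0.5]; seeded multistart Nelder-Mead for
#' the Wilson energies (u12, u21) in [-1e5, 1e5] J mol^-1 under the
#' Wong-Sandler or Huron-Vidal rules.  Records where the equifugacity solve
#' fails at a trial point are excluded from the objective with a warning and
#' reported in the fit.
#'
#' @param dataset an `sc_dataset` (>= 2 records).
#' @param kind mixing-rule kind to fit (see [mixing_rule()]).
#' @param n_starts multistart count for the 2-D Wilson search (default 8;
#'   ignored for vdW).
#' @param seed RNG seed for the multistart (default 20230207).
#' @param y0 initial mole-fraction guess passed to the solver.
#' @return object of class `eos_fit`: optimised `rule`, `ald_y`,
#'   `aard_percent`, `predicted_y`, `n_failed`, `optimizer_report`.
#' @export
fit_eos <- function(dataset, kind = c("vdw", "wong_sandler", "huron_vidal"),
                    n_starts = 8L, seed = 20230207L, y0 = 1e-5) {
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "sc_dataset"))
  r <- dataset$records
  if (nrow(r) < 2L) stop_scsolub("usage_error", "need at least 2 records")
  Tv <- r$temperature_K
  Pv <- r$pressure_MPa
  y_exp <- r$mole_fraction

  ## state independent of the binary parameters, computed once
  temps <- unique(Tv)
  p1s <- lapply(temps, function(tt) pure_pr_params(dataset$solvent, tt))
  p2s <- lapply(temps, function(tt) pure_pr_params(dataset$solute, tt))
  names(p1s) <- names(p2s) <- as.character(temps)
  fsv <- vapply(seq_along(Tv), function(i) {
    ref <- pure_liquid_reference(dataset$solute, Tv[i], Pv[i])
    solid_fugacity(dataset$solute, Tv[i], Pv[i], ref$fugacity, ref$molar_volume)
  }, 0)

  warm <- rep(y0, length(Tv))  # warm-started iterates across objective calls
  n_eval <- 0L
  predict_all <- function(rule) {
    n_eval <<- n_eval + 1L
    vapply(seq_along(Tv), function(i) {
      key <- as.character(Tv[i])
      s <- .solve_y(rule, Tv[i], Pv[i] * 1e6, fsv[i], p1s[[key]], p2s[[key]],
                    y0 = warm[i])
      if (s$converged && is.finite(s$y)) warm[i] <<- s$y
      if (s$converged) s$y else NA_real_
    }, 0)
  }
  objective_for <- function(make_rule) function(par) {
    yc <- predict_all(make_rule(par))
    ok <- is.finite(yc)
    if (sum(ok) < 2L) return(1e4)
    ald_y(y_exp[ok], yc[ok]) + 10 * sum(!ok)  # failed points penalised
  }

  if (kind == "vdw") {
    make_rule <- function(k) mixing_rule("vdw", k12 = k)
    obj <- objective_for(make_rule)
    opt <- stats::optimize(obj, c(-0.5, 0.5), tol = 1e-7)
    best_par <- opt$minimum
    report <- list(objective_value = opt$objective, seed = NA_integer_,
                   starts = 1L, function_evaluations = n_eval)
  } else {
    make_rule <- function(u) mixing_rule(kind, ge_model = ge_wilson(u[1], u[2]))
    obj <- objective_for(make_rule)
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    starts <- rbind(c(0, 0), c(2e4, 2e4), c(-2e4, 2e4),
                    matrix(stats::runif(2 * max(0L, n_starts - 3L), -1e5, 1e5),
                           ncol = 2))
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      o <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-8))
      if (is.null(best) || o$value < best$value) best <- o
    }
    best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-10))
    best_par <- best$par
    report <- list(objective_value = best$value, seed = seed,
                   starts = nrow(starts), function_evaluations = n_eval)
  }

  rule_opt <- make_rule(best_par)
  yc <- predict_all(rule_opt)
  ok <- is.finite(yc)
  if (any(!ok)) {
    warning(sprintf("%d of %d equifugacity solves failed at the optimum and were excluded",
                    sum(!ok), length(ok)))
  }
  structure(list(
    rule = rule_opt,
    ald_y = ald_y(y_exp[ok], yc[ok]),
    aard_percent = aard(y_exp[ok], yc[ok]),
    predicted_y = yc,
    n_failed = sum(!ok),
    optimizer_report = report
  ), class = "eos_fit")
}

#' @export
print.eos_fit <- function(x, ...) {
  cat(sprintf("<eos_fit> %s: ALD-y = %.3f, AARD = %.1f%%",
              x$rule$kind, x$ald_y, x$aard_percent))
  if (x$n_failed) cat(sprintf(" (%d records excluded)", x$n_failed))
  cat("\n")
  print(x$rule)
  invisible(x)
}
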