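test_that("pure PR parameters behave at the critical point and in omega", {
  slv <- solvent_card()
  at_tc <- pure_pr_params(slv, slv$critical_temperature)
  expect_equal(at_tc$alpha, 1)

  p308 <- pure_pr_params(slv, 308)
  expect_gt(p308$attraction, 0)
  expect_gt(p308$covolume, 0)

  mk <- function(w) solvent_card(acentric_factor = max(w, 1e-9))
  a0 <- pure_pr_params(structure(list(critical_temperature = 304.21,
                                      critical_pressure = 7.383,
                                      acentric_factor = 0), class = "solvent_card"),
                       250)
  a5 <- pure_pr_params(structure(list(critical_temperature = 304.21,
                                      critical_pressure = 7.383,
                                      acentric_factor = 0.5), class = "solvent_card"),
                       250)
  expect_gt(a5$alpha, a0$alpha)
})

test_that("volume roots satisfy the pressure equation to 1e-8", {
  ds <- study()
  for (card in list(ds$solvent, ds$solute)) {
    p <- pure_pr_params(card, 308)
    roots <- solve_volume(308, 12, p$attraction, p$covolume)
    for (V in roots$volume) {
      P_back <- RGAS * 308 / (V - p$covolume) -
        p$attraction / (V * (V + p$covolume) + p$covolume * (V - p$covolume))
      expect_equal(P_back, 12e6, tolerance = 1e-8)
      expect_gt(V, p$covolume)
    }
  }
})

test_that("the ideal-gas limit is recovered at low pressure", {
  p <- pure_pr_params(solvent_card(), 400)
  roots <- solve_volume(400, 1e-3, p$attraction, p$covolume)
  expect_equal(nrow(roots), 1L)
  expect_equal(roots$Z, 1, tolerance = 1e-3)
})

test_that("pure PR density of CO2 is within 10% of the NIST table value", {
  rho <- pr_co2_density(solvent_card(), 308, 12)
  expect_lt(abs(rho - 769) / 769, 0.10)
})

test_that("identical components are indistinguishable under all rules", {
  tc <- twin_cards()
  rules <- list(
    mixing_rule("vdw", k12 = 0),
    mixing_rule("wong_sandler", ge_model = ge_ideal()),
    mixing_rule("huron_vidal", ge_model = ge_ideal())
  )
  p_pure <- pure_pr_params(tc$solvent, 320)
  A <- p_pure$attraction * 15e6 / (RGAS * 320)^2
  B <- p_pure$covolume * 15e6 / (RGAS * 320)
  lnphi_pure <- scsolub:::.pr_gres(scsolub:::.pr_pick_root(A, B), A, B)
  for (rule in rules) {
    lp <- fugacity_coefficients(320, 15, c(0.37, 0.63), rule,
                                tc$solvent, tc$solute)
    expect_equal(lp[1], lp[2], tolerance = 1e-6)
    expect_equal(lp[1], lnphi_pure, tolerance = 1e-5)
  }
})

test_that("closed-form vdW fugacities match the finite-difference oracle", {
  ds <- study()
  rule <- mixing_rule("vdw", k12 = -0.0378)
  p1 <- pure_pr_params(ds$solvent, 318)
  p2 <- pure_pr_params(ds$solute, 318)
  for (x2 in c(1e-5, 1e-3, 0.05)) {
    x <- c(1 - x2, x2)
    cf <- scsolub:::.lnphi_vdw(318, 18e6, x, p1, p2, -0.0378)
    fd <- scsolub:::.lnphi_fd(rule, 318, 18e6, x, p1, p2)
    expect_equal(cf, fd, tolerance = 1e-6)
  }
})

test_that("fugacity coefficients obey the Gibbs-Duhem relation", {
  ds <- study()
  for (rule in list(mixing_rule("vdw", k12 = 0.02),
                    mixing_rule("wong_sandler", ge_model = ge_wilson(2000, 8000)),
                    mixing_rule("huron_vidal", ge_model = ge_wilson(2000, 8000)))) {
    x2 <- 0.2; h <- 1e-5
    lp_p <- fugacity_coefficients(318, 18, c(1 - x2 - h, x2 + h), rule,
                                  ds$solvent, ds$solute)
    lp_m <- fugacity_coefficients(318, 18, c(1 - x2 + h, x2 - h), rule,
                                  ds$solvent, ds$solute)
    gd <- (1 - x2) * (lp_p[1] - lp_m[1]) / (2 * h) +
      x2 * (lp_p[2] - lp_m[2]) / (2 * h)
    expect_lt(abs(gd), 1e-3)
  }
})

test_that("Wilson model reduces to the ideal solution at zero interaction", {
  g <- ge_wilson(0, 0)
  expect_equal(g$fun(318, c(0.7, 0.3)), 0)
  expect_equal(ge_ideal()$fun(318, c(0.5, 0.5)), 0)
  ds <- study()
  lp_wilson0 <- fugacity_coefficients(318, 18, c(0.9999, 1e-4),
                                      mixing_rule("huron_vidal",
                                                  ge_model = ge_wilson(0, 0)),
                                      ds$solvent, ds$solute)
  lp_ideal <- fugacity_coefficients(318, 18, c(0.9999, 1e-4),
                                    mixing_rule("huron_vidal",
                                                ge_model = ge_ideal()),
                                    ds$solvent, ds$solute)
  expect_equal(lp_wilson0, lp_ideal, tolerance = 1e-10)
})

test_that("Wong-Sandler does not collapse onto vdW for distinct components", {
  ds <- study()
  lp_ws <- fugacity_coefficients(318, 18, c(0.999, 1e-3),
                                 mixing_rule("wong_sandler", ge_model = ge_ideal()),
                                 ds$solvent, ds$solute)
  lp_vdw <- fugacity_coefficients(318, 18, c(0.999, 1e-3),
                                  mixing_rule("vdw", k12 = 0),
                                  ds$solvent, ds$solute)
  expect_gt(abs(lp_ws[2] - lp_vdw[2]), 0.1)
})

test_that("solid fugacity honours the melting-point identity and sign", {
  card <- study()$solute
  Tm <- card$melt_temperature
  Vs <- card$solid_molar_volume * 1e-6
  fL <- 1e3
  expect_equal(solid_fugacity(card, Tm, 0.101325, fL, Vs), fL, tolerance = 1e-6)
  expect_lt(solid_fugacity(card, 308, 0.101325, fL, Vs), fL)
  expect_error(solid_fugacity(card, Tm + 10, 10, fL, Vs),
               class = "scsolub_domain_error")

  ## direct substitution at 308 K, 12 MPa with an EoS-supplied reference
  ref <- pure_liquid_reference(card, 308, 12)
  fs <- solid_fugacity(card, 308, 12, ref$fugacity, ref$molar_volume)
  lnr <- 23.7e3 / (RGAS * Tm) * (1 - Tm / 308) +
    (Vs - ref$molar_volume) * (12e6 - 101325) / (RGAS * 308)
  expect_equal(fs, ref$fugacity * exp(lnr), tolerance = 1e-12)
})

test_that("equifugacity solution is a verified fixed point", {
  ds <- study()
  rule <- mixing_rule("vdw", k12 = 0.05)
  res <- solve_solubility(ds$solute, ds$solvent, 318, 18, rule)
  expect_true(res$converged)
  expect_gt(res$mole_fraction, 0)
  expect_lt(res$mole_fraction, 1)
  ## defining property: f^SC(y*) = f^S
  lp <- fugacity_coefficients(318, 18, c(1 - res$mole_fraction,
                                         res$mole_fraction), rule,
                              ds$solvent, ds$solute)
  f_sc <- res$mole_fraction * exp(lp[2]) * 18e6
  expect_equal(log(f_sc), log(res$solid_fugacity), tolerance = 1e-8)

  ## brute-force scan attains its minimum at the returned y
  ygrid <- 10^seq(-9, -2, length = 600)
  resid <- vapply(ygrid, function(yy) {
    lp <- fugacity_coefficients(318, 18, c(1 - yy, yy), rule,
                                ds$solvent, ds$solute)
    abs(log(yy) + lp[2] + log(18e6) - log(res$solid_fugacity))
  }, 0)
  y_scan <- ygrid[which.min(resid)]
  expect_equal(log(y_scan), log(res$mole_fraction), tolerance = 0.05)
})

test_that("predicted solubility varies continuously along an isotherm", {
  ds <- study()
  fit <- study_eos_fit("vdw")
  y <- vapply(c(12, 15, 18, 21, 24, 27), function(P)
    solve_solubility(ds$solute, ds$solvent, 308, P, fit$rule)$mole_fraction, 0)
  expect_true(all(is.finite(y)))
  expect_true(all(abs(diff(log(y))) < 1.5))
})

test_that("fitted vdW isotherms exhibit a crossover region", {
  ds <- study()
  fit <- study_eos_fit("vdw")
  y308 <- vapply(c(12, 27), function(P)
    solve_solubility(ds$solute, ds$solvent, 308, P, fit$rule)$mole_fraction, 0)
  y338 <- vapply(c(12, 27), function(P)
    solve_solubility(ds$solute, ds$solvent, 338, P, fit$rule)$mole_fraction, 0)
  ## opposite temperature ordering at the two pressure extremes
  expect_true((y308[1] - y338[1]) * (y308[2] - y338[2]) < 0)
})

test_that("self-generated EoS data recover the binary parameter", {
  ds <- study()
  truth <- synthetic_spec(mixing_rule("vdw", k12 = 0.06), noise_sigma = 0,
                          replicates = 1,
                          temperature_grid = c(308, 328),
                          pressure_grid = c(12, 18, 24))
  synth <- generate_dataset(truth, solute = ds$solute, solvent = ds$solvent)
  fit <- fit_eos(synth, "vdw")
  expect_equal(fit$rule$k12, 0.06, tolerance = 1e-4)
  expect_lt(fit$ald_y, 1e-6)
})

test_that("ald_y matches its definition and is zero for a perfect predictor", {
  y <- c(1e-6, 5e-6, 2e-5)
  expect_equal(ald_y(y, y), 0)
  expect_equal(ald_y(c(1e-5), c(1e-6)), 1)
  expect_error(ald_y(y, y[1:2]), class = "scsolub_usage_error")
})

test_that("mixing-rule constructors validate their arguments", {
  expect_error(mixing_rule("vdw"), class = "scsolub_usage_error")
  expect_error(mixing_rule("vdw", k12 = 0.1, ge_model = ge_ideal()),
               class = "scsolub_usage_error")
  expect_error(mixing_rule("wong_sandler"), class = "scsolub_usage_error")
  expect_error(mixing_rule("wong_sandler", k12 = 0.1),
               class = "scsolub_usage_error")
  rule <- mixing_rule("huron_vidal", ge_model = ge_custom(function(T, x) 0))
  expect_s3_class(rule, "mixing_rule")
})
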