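test_that("Chrastil evaluation matches hand substitution", {
  rec <- data.frame(temperature_K = 308, pressure_MPa = 12,
                    co2_density_kg_m3 = 769)
  pars <- published_params$chrastil
  S <- evaluate_model("chrastil", pars, rec)
  ## hand: exp(7.5314*log(769) - 4860.461/308 - 38.0736) = 0.02220408
  expect_equal(S, 0.02220408, tolerance = 1e-6)
})

test_that("all-zero parameters give unit response in each model's own units", {
  rec <- data.frame(temperature_K = 318, pressure_MPa = 15,
                    co2_density_kg_m3 = 744)
  Pbar <- 150
  expect_equal(evaluate_model("chrastil", rep(0, 3), rec), 1)    # S = 1
  expect_equal(evaluate_model("kj", rep(0, 3), rec), 1)          # y = 1
  expect_equal(evaluate_model("belghait", rep(0, 8), rec), 1)
  expect_equal(evaluate_model("mst", rep(0, 3), rec), 1 / Pbar)  # yP = 1
  expect_equal(evaluate_model("bartle", rep(0, 3), rec), 1 / Pbar) # yP/Pref = 1
})

test_that("Bartle's density term vanishes at the reference density", {
  rec <- data.frame(temperature_K = 328, pressure_MPa = 20,
                    co2_density_kg_m3 = 700)
  y_a <- evaluate_model("bartle", c(11.9754, 0.0117, -6335.4073), rec)
  y_b <- evaluate_model("bartle", c(11.9754, -5, -6335.4073), rec)
  expect_equal(y_a, y_b)
})

test_that("evaluation rejects wrong arity and non-positive density", {
  rec <- data.frame(temperature_K = 318, pressure_MPa = 15,
                    co2_density_kg_m3 = 744)
  expect_error(evaluate_model("chrastil", 1:4, rec), class = "scsolub_usage_error")
  rec$co2_density_kg_m3 <- -5
  expect_error(evaluate_model("chrastil", c(1, 1, 1), rec),
               class = "scsolub_evaluation_error")
})

test_that("aard matches hand arithmetic and is scale invariant", {
  expect_equal(aard(c(1, 2), c(1, 2)), 0)
  expect_equal(aard(c(1, 2), c(1.1, 1.8)), 10)
  y <- c(0.4, 1.1, 2.7) * 1e-5
  yc <- c(0.5, 1.0, 2.2) * 1e-5
  expect_equal(aard(y, yc), aard(y * 1e7, yc * 1e7))
  expect_error(aard(c(1, 2), 1), class = "scsolub_usage_error")
  expect_error(aard(c(0, 2), c(1, 2)), class = "scsolub_usage_error")
})

test_that("fitted AARD never exceeds the published optimum by more than 0.2 pp", {
  ds <- study()
  for (m in names(published_params)) {
    fit <- study_fit(m)
    y_at_published <- predict_mole_fraction(fit$spec, published_params[[m]],
                                            ds$records, ds$solute, ds$solvent)
    aard_published <- aard(ds$records$mole_fraction, y_at_published)
    expect_lte(fit$aard_percent, aard_published + 0.2)
  }
})

test_that("the reported optimum is never worse than a user-supplied start", {
  ds <- study()
  f <- fit_model("chrastil", ds, n_restarts = 2,
                 start = published_params$chrastil)
  y_at_start <- predict_mole_fraction(f$spec, published_params$chrastil,
                                      ds$records, ds$solute, ds$solvent)
  expect_lte(f$aard_percent, aard(ds$records$mole_fraction, y_at_start))
})

test_that("fit reports residuals, convergence and deterministic seeding", {
  ds <- study()
  f1 <- fit_model("kj", ds, n_restarts = 4, seed = 7)
  f2 <- fit_model("kj", ds, n_restarts = 4, seed = 7)
  expect_identical(f1$parameters, f2$parameters)
  expect_length(f1$residuals, nrow(ds$records))
  expect_true(f1$optimizer_report$converged)
  expect_gte(f1$aard_percent, 0)
  expect_error(fit_model("kj", solubility_dataset(ds$records[1:3, ],
                                                  ds$solute, ds$solvent)),
               class = "scsolub_fit_error")
})

test_that("enthalpies follow from the temperature coefficients exactly", {
  ds <- study()
  fit_c <- study_fit("chrastil")
  fit_b <- study_fit("bartle")

  ## at the published coefficients the published enthalpies are recovered
  fake_c <- fit_c; fake_c$parameters[["a1"]] <- -4860.461
  fake_b <- fit_b; fake_b$parameters[["a2"]] <- -6335.4073
  e <- enthalpies(fake_c, fake_b)
  expect_equal(e$total, 40.41, tolerance = 1e-3)
  expect_equal(e$vaporization, 52.67, tolerance = 1e-3)
  expect_equal(e$solvation, e$total - e$vaporization)

  fake_c$parameters[["a1"]] <- 0; fake_b$parameters[["a2"]] <- 0
  e0 <- enthalpies(fake_c, fake_b)
  expect_equal(c(e0$total, e0$vaporization, e0$solvation), c(0, 0, 0))

  expect_error(enthalpies(fit_b, fit_b), class = "scsolub_usage_error")
  expect_error(enthalpies(fit_c, fit_c), class = "scsolub_usage_error")
})

test_that("exact Chrastil data collapse to a perfect consistency line", {
  truth <- synthetic_spec(list(model = "chrastil",
                               parameters = published_params$chrastil),
                          noise_sigma = 0, replicates = 1)
  ds <- generate_dataset(truth)
  fit <- fit_model("chrastil", ds, n_restarts = 0)
  ct <- consistency_test("chrastil", fit, ds)
  expect_gt(ct$r_squared, 1 - 1e-10)
})

test_that("study data collapse well; shuffled data much worse", {
  ds <- study()
  fit <- study_fit("chrastil")
  ct <- consistency_test("chrastil", fit, ds)
  expect_gt(ct$r_squared, 0.9)

  shuffled <- ds
  set.seed(11)
  shuffled$records$mole_fraction <- sample(shuffled$records$mole_fraction)
  shuffled$records$mass_solubility_g_L <- mole_fraction_to_mass_solubility(
    shuffled$records$mole_fraction, shuffled$records$co2_density_kg_m3,
    ds$solvent$molar_mass, ds$solute$molar_mass)
  ct_shuf <- consistency_test("chrastil", fit, shuffled)
  expect_lt(ct_shuf$r_squared, ct$r_squared - 0.3)

  ct_mst <- consistency_test("mst", study_fit("mst"), ds)
  expect_gt(ct_mst$r_squared, 0.9)
  expect_true(ct_mst$r_squared <= 1)
})

test_that("fitted Bian and Belghait isotherms cross between 16 and 27 MPa", {
  ds <- study()
  temps <- sort(unique(ds$records$temperature_K))
  for (m in c("bian", "belghait")) {
    fit <- study_fit(m)
    crossings <- c()
    for (i in seq_len(length(temps) - 1)) {
      crossings <- c(crossings,
                     crossover_pressure(fit, ds, temps[i], temps[i + 1]))
    }
    crossings <- crossings[is.finite(crossings)]
    expect_gt(length(crossings), 0)
    expect_true(all(crossings >= 16 & crossings <= 27),
                info = sprintf("%s crossings: %s", m,
                               paste(round(crossings, 2), collapse = ", ")))
  }
})
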