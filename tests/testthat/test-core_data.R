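test_that("molar mass follows from the empirical formula", {
  expect_equal(molar_mass("CO2"), 44.009, tolerance = 1e-6)
  expect_equal(molar_mass("C24H29N7O2"), 447.543, tolerance = 1e-6)
  expect_error(molar_mass("C24Xx2"), class = "scsolub_parse_error")
})

test_that("packaged study has the full grid and the reported extremes", {
  ds <- study()
  r <- ds$records
  expect_equal(nrow(r), 24L)
  expect_setequal(unique(r$temperature_K), c(308, 318, 328, 338))
  expect_setequal(unique(r$pressure_MPa), c(12, 15, 18, 21, 24, 27))

  row1 <- r[r$temperature_K == 308 & r$pressure_MPa == 12, ]
  expect_equal(row1$co2_density_kg_m3, 769)
  expect_equal(row1$mole_fraction, 0.391e-5)

  imin <- which.min(r$mole_fraction)
  expect_equal(r$mole_fraction[imin], 0.081e-5)
  expect_equal(c(r$temperature_K[imin], r$pressure_MPa[imin]), c(338, 12))
  imax <- which.max(r$mole_fraction)
  expect_equal(r$mole_fraction[imax], 2.027e-5)
  expect_equal(c(r$temperature_K[imax], r$pressure_MPa[imax]), c(338, 27))

  expect_equal(ds$solute$molar_mass, 447.543, tolerance = 1e-6)
  expect_equal(ds$solute$melt_temperature, 545.19)
  expect_equal(ds$solute$critical_temperature, 1254.31)
  expect_equal(ds$solute$critical_pressure, 1.6069)
  expect_equal(ds$solute$acentric_factor, 0.4660)
  expect_equal(ds$solute$solid_molar_volume, 303.85)
  expect_equal(ds$solute$fusion_enthalpy, 23.7)
})

test_that("every fixture isotherm is strictly increasing in pressure", {
  r <- study()$records
  for (tt in unique(r$temperature_K)) {
    y <- r$mole_fraction[r$temperature_K == tt]
    expect_true(all(diff(y) > 0), info = sprintf("T = %g K", tt))
  }
})

test_that("fixture S and y are consistent through the loop relation", {
  ds <- study()
  r <- ds$records
  s_loop <- mole_fraction_to_mass_solubility(
    r$mole_fraction, r$co2_density_kg_m3,
    ds$solvent$molar_mass, ds$solute$molar_mass)
  expect_true(all(abs(r$mass_solubility_g_L - s_loop) / s_loop < 0.02))
})

test_that("as-reported mass solubilities flag only the heavily rounded row", {
  ds <- study()
  rep_file <- system.file("extdata", "palbociclib_reported_S.csv",
                          package = "scsolub")
  rep_tab <- read.csv(rep_file)
  key_ds <- paste(ds$records$temperature_K, ds$records$pressure_MPa)
  key_rep <- paste(rep_tab$temperature_K, rep_tab$pressure_MPa)
  flags <- flag_inconsistent_solubility(
    ds, rep_tab$reported_S_g_L[match(key_ds, key_rep)])
  bad <- flags[flags$flagged, ]
  expect_equal(nrow(bad), 1L)
  expect_equal(c(bad$temperature_K, bad$pressure_MPa), c(338, 12))
  expect_lt(abs(bad$rel_dev), 0.035)
})

test_that("schema and validation errors are specific", {
  ds <- study()
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(load_dataset(empty, "csv", solute = ds$solute),
               class = "scsolub_schema_error")

  partial <- tempfile(fileext = ".csv")
  write.csv(data.frame(temperature_K = 308, pressure_MPa = 12), partial,
            row.names = FALSE)
  err <- expect_error(load_dataset(partial, "csv", solute = ds$solute),
                      class = "scsolub_schema_error")
  expect_match(conditionMessage(err), "co2_density_kg_m3")

  bad <- ds$records[1, ]
  bad$mole_fraction <- 1.5
  err2 <- expect_error(
    solubility_dataset(bad, ds$solute, ds$solvent),
    class = "scsolub_validation_error")
  expect_match(conditionMessage(err2), "mole_fraction")

  dup <- ds$records[c(1, 1), ]
  expect_error(solubility_dataset(dup, ds$solute, ds$solvent),
               class = "scsolub_validation_error")
})

test_that("datasets round-trip through CSV and JSON", {
  ds <- study()
  csv <- tempfile(fileext = ".csv")
  write_dataset(ds, csv, "csv")
  back <- load_dataset(csv, "csv", solute = ds$solute, solvent = ds$solvent)
  expect_identical(back$records, ds$records)

  js <- tempfile(fileext = ".json")
  write_dataset(ds, js, "json")
  back2 <- load_dataset(js, "json")
  expect_equal(back2$records, ds$records)
  expect_equal(back2$solute$molar_mass, ds$solute$molar_mass)
})

test_that("property cards enforce their invariants", {
  expect_error(
    solute_card("x", "C2H6", melt_temperature = 700, fusion_enthalpy = 10,
                critical_temperature = 600, critical_pressure = 3,
                acentric_factor = 0.2, solid_molar_volume = 100),
    class = "scsolub_validation_error")
  expect_error(solvent_card(molar_mass = -1), class = "scsolub_validation_error")
})
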