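# Composition-basis and solute-unit conversions.

test_that("solvent-basis conversions hit known values and endpoints", {
  # equal molar masses: symmetry point
  expect_equal(solvent_mole_to_mass(0.5, 40, 40), 0.5)
  # endpoints preserved
  expect_equal(solvent_mole_to_mass(c(0, 1), 46.07, 18.02), c(0, 1))
  expect_equal(solvent_mass_to_mole(c(0, 1), 46.07, 18.02), c(0, 1))
  expect_equal(solvent_mass_to_volume(c(0, 1), 0.789, 0.997), c(0, 1))
  # ethanol/water: x = 0.5 -> w = 23.035 / 32.045
  expect_equal(solvent_mole_to_mass(0.5, 46.07, 18.02), 23.035 / 32.045,
               tolerance = 1e-12)
  # equal densities: volume fraction equals mass fraction
  expect_equal(solvent_mass_to_volume(0.37, 0.9, 0.9), 0.37)
  # ethanol/water densities at w = 0.5
  expect_equal(solvent_mass_to_volume(0.5, 0.789, 0.997),
               (0.5 / 0.789) / (0.5 / 0.789 + 0.5 / 0.997),
               tolerance = 1e-12)
})

test_that("all basis conversion pairs are mutual inverses and monotone", {
  w <- seq(0.01, 0.99, length.out = 23)
  M1 <- 46.07; M2 <- 18.02; r1 <- 0.789; r2 <- 0.997
  expect_equal(solvent_mass_to_mole(solvent_mole_to_mass(w, M1, M2), M1, M2),
               w, tolerance = 1e-13)
  expect_equal(solvent_mole_to_mass(solvent_mass_to_mole(w, M1, M2), M1, M2),
               w, tolerance = 1e-13)
  expect_equal(
    solvent_volume_to_mass(solvent_mass_to_volume(w, r1, r2), r1, r2),
    w, tolerance = 1e-13)
  # strict monotonicity
  expect_true(all(diff(solvent_mole_to_mass(w, M1, M2)) > 0))
  expect_true(all(diff(solvent_mass_to_volume(w, r1, r2)) > 0))
})

test_that("mole fraction <-> molarity matches the mass-balance oracle", {
  x_d <- 1e-3; x1m <- 0; Md <- 250; M1 <- 46.07; M2 <- 18.02; rho <- 1.0
  C <- solute_molefrac_to_molar(x_d, x1m, Md, M1, M2, rho)
  expect_equal(C, oracle_molefrac_to_molar(x_d, x1m, Md, M1, M2, rho),
               tolerance = 1e-12)
  # pure-water binary reduction
  expect_equal(C, 1000 * x_d * rho / (x_d * Md + (1 - x_d) * M2),
               tolerance = 1e-12)
  # round trip at many points
  xs <- 10^seq(-6, -1.2, length.out = 11)
  x1s <- seq(0, 1, length.out = 11)
  C2 <- solute_molefrac_to_molar(xs, x1s, Md, M1, M2, rho)
  expect_equal(solute_molar_to_molefrac(C2, x1s, Md, M1, M2, rho), xs,
               tolerance = 1e-10)
  # density is mandatory
  expect_error(solute_molefrac_to_molar(x_d, x1m, Md, M1, M2, NA_real_),
               "density")
})

test_that("molar <-> g/L is the exact molar-mass factor", {
  # the sulfanilamide-scale pairing: 16.2 mol/L x 172.20 g/mol
  expect_equal(molar_to_gram_per_liter(16.2, 172.20), 2789.64)
  expect_equal(molar_to_gram_per_liter(0, 101), 0)
  C <- c(1e-6, 0.02, 16.2)
  expect_identical(gram_per_liter_to_molar(molar_to_gram_per_liter(C, 250),
                                           250), C)
})

test_that("unit codes decode to the 3x3 table", {
  decoded <- lapply(1:9, unit_code)
  expect_equal(vapply(decoded, `[[`, character(1), "solvent_basis"),
               rep(c("mole", "mass", "volume"), each = 3))
  expect_equal(vapply(decoded, `[[`, character(1), "solute_unit"),
               rep(c("mole_fraction", "molar", "gram_per_liter"), times = 3))
  expect_error(unit_code(10), "1..9")
})

test_that("convert_dataset: identity code, g/L = molar x Md, round trips", {
  ds <- generate_dataset(generator_config(seed = 5, grid_basis = "mole"))
  # code 1 on a (mole basis, mole fraction) dataset changes nothing
  conv1 <- convert_dataset(ds, 1)
  expect_equal(conv1$data$w1, ds$records$w1)
  expect_equal(conv1$data$xm, ds$records$solubility)
  expect_equal(conv1$data$T, ds$records$temperature)

  # code 3 = code 2 scaled by the drug molar mass, record-wise
  conv2 <- convert_dataset(ds, 2)
  conv3 <- convert_dataset(ds, 3)
  expect_equal(conv3$data$xm, conv2$data$xm * ds$drug$molar_mass,
               tolerance = 1e-14)
  expect_equal(conv3$data$x1T, conv2$data$x1T * ds$drug$molar_mass,
               tolerance = 1e-14)

  # code 1 -> molar -> back to mole fraction recovers the original
  x_back <- solute_molar_to_molefrac(
    conv2$data$xm, conv1$data$w1, ds$drug$molar_mass,
    ds$solvent1$molar_mass, ds$solvent2$molar_mass, ds$records$rho_sat)
  expect_equal(x_back, ds$records$solubility, tolerance = 1e-10)

  # conversion never changes record count or temperatures; endpoints map to
  # endpoints in every basis
  for (cd in 1:9) {
    cv <- convert_dataset(ds, cd)
    expect_equal(nrow(cv$data), nrow(ds$records))
    expect_equal(cv$data$T, ds$records$temperature)
    expect_equal(cv$data$w1[ds$records$w1 == 0], rep(0, 3))
    expect_equal(cv$data$w1[ds$records$w1 == 1], rep(1, 3))
    expect_true(all(cv$data$xm > 0))
  }
})

test_that("missing density fails loudly for volumetric targets only", {
  ds <- make_tiny_dataset(rho_sat = NA_real_)
  expect_s3_class(convert_dataset(ds, 1), "converted_dataset")
  expect_s3_class(convert_dataset(ds, 7), "converted_dataset")
  expect_error(convert_dataset(ds, 2), "missing at record")
  expect_error(convert_dataset(ds, 6), "density")
})

test_that("mixture density table defaults a missing saturated density", {
  ds <- make_tiny_dataset(rho_sat = NA_real_)
  grid <- seq(0, 1, by = 0.25)
  tab <- expand.grid(w1_mass = grid, temperature = c(298.2, 308.2, 318.2))
  tab$rho <- 1 / (tab$w1_mass / 0.789 + (1 - tab$w1_mass) / 0.997)
  ds$mixture_density_table <- tab
  conv <- convert_dataset(ds, 2)
  expect_true(all(is.finite(conv$data$xm)) && all(conv$data$xm > 0))
})
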