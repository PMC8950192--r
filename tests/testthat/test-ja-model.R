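# Regression construction, fitting, prediction, back-calculation.

J_SD_ACN_MEOH <- c(897.693, -1417.112, 1671.752)  # literature three-term fit
J_FIVE_TERM <- c(934.547, -937.019, 1130.686, -1443.763, 848.997)

test_that("build_regression excludes pure-solvent rows and zeroes odd columns", {
  cfg <- generator_config(noise_sigma = 0, grid = c(0, 0.3, 0.5, 0.7, 1),
                          grid_basis = "mole")
  conv <- convert_dataset(generate_dataset(cfg), 1)
  sys <- build_regression(conv, np = 2)
  expect_equal(length(sys$y), 9L)           # 3 mixed compositions x 3 T
  expect_true(all(conv$data$w1[sys$rows] > 0 & conv$data$w1[sys$rows] < 1))
  # at w1 = w2 = 0.5 the higher-order regressors vanish exactly
  at_half <- conv$data$w1[sys$rows] == 0.5
  expect_true(all(sys$X[at_half, c("J1", "J2")] == 0))
  # noise-free response equals the forward evaluation design %*% J
  expect_equal(sys$y, drop(sys$X %*% J_SD_ACN_MEOH), tolerance = 1e-10)
})

test_that("underdetermined and rank-deficient designs raise named errors", {
  cfg <- generator_config(noise_sigma = 0, grid = c(0, 0.35, 0.5, 0.65, 1),
                          grid_basis = "mole", temperatures = 298.2)
  conv <- convert_dataset(generate_dataset(cfg), 1)
  expect_error(build_regression(conv, np = 4), "underdetermined")

  cfg2 <- generator_config(noise_sigma = 0, grid = c(0, 0.3, 0.3, 0.3, 1),
                           grid_basis = "mole", temperatures = 298.2)
  conv2 <- convert_dataset(generate_dataset(cfg2), 1)
  expect_error(fit_ja(conv2, np = 2), "collinear")
})

test_that("noise-free fits recover the generating coefficients", {
  # three-term literature constants to >= 8 significant digits
  cfg <- generator_config(J_true = J_SD_ACN_MEOH, noise_sigma = 0,
                          grid_basis = "mole")
  fit <- fit_ja(convert_dataset(generate_dataset(cfg), 1), np = 2)
  expect_equal(unname(fit$coefficients), J_SD_ACN_MEOH, tolerance = 1e-9)

  # five-term constants with np = 4
  cfg5 <- generator_config(J_true = J_FIVE_TERM, noise_sigma = 0,
                           grid = seq(0, 1, by = 0.05), grid_basis = "mole")
  fit5 <- fit_ja(convert_dataset(generate_dataset(cfg5), 1), np = 4)
  expect_equal(unname(fit5$coefficients), J_FIVE_TERM, tolerance = 1e-9)
})

test_that("all-zero response reduces the model to ideal log-linear mixing", {
  fit <- fit_ja(convert_dataset(make_tiny_dataset(), 4), np = 2)
  expect_equal(unname(fit$coefficients), c(0, 0, 0), tolerance = 1e-10)
  conv <- convert_dataset(make_tiny_dataset(), 4)
  bc <- back_calculate(fit, conv)
  expect_equal(bc$x_cal, bc$x_exp, tolerance = 1e-9)
})

test_that("coefficients match the brute-force normal-equations oracle", {
  # a deliberately small 4-point single-temperature system
  cfg <- generator_config(noise_sigma = 0.1, seed = 17,
                          grid = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                          grid_basis = "mole", temperatures = 298.2)
  conv <- convert_dataset(generate_dataset(cfg), 1)
  sys <- build_regression(conv, np = 2)
  fit <- fit_ja(conv, np = 2)
  expect_equal(unname(fit$coefficients),
               unname(oracle_normal_equations(sys$X, sys$y)),
               tolerance = 1e-10)
})

test_that("prediction honours the boundary identities and model nesting", {
  cfg <- generator_config(seed = 2, grid_basis = "mole")
  conv <- convert_dataset(generate_dataset(cfg), 1)
  fit <- fit_ja(conv, np = 2)
  expect_identical(predict_ln_solubility(fit, 1, 300, -3.5, -9.1), -3.5)
  expect_identical(predict_ln_solubility(fit, 0, 300, -3.5, -9.1), -9.1)

  # all-J-zero fit equals the ideal mixing rule everywhere
  fit0 <- fit
  fit0$coefficients[] <- 0
  w <- seq(0, 1, by = 0.1)
  expect_equal(predict_ln_solubility(fit0, w, 310, -2, -8),
               yalkowsky_predict(w, -2, -8))
  expect_equal(yalkowsky_predict(0.5, -4, -4), -4)
  expect_equal(yalkowsky_predict(1, -2, -9), -2)

  # forward evaluation agrees with explicit hand arithmetic
  w1 <- 0.3; Tk <- 308.2; lx1 <- -4.2; lx2 <- -9.7; w2 <- 1 - w1
  hand <- w1 * lx1 + w2 * lx2 + (w1 * w2 / Tk) *
    (J_FIVE_TERM[1] + J_FIVE_TERM[2] * (w1 - w2) +
     J_FIVE_TERM[3] * (w1 - w2)^2 + J_FIVE_TERM[4] * (w1 - w2)^3 +
     J_FIVE_TERM[5] * (w1 - w2)^4)
  expect_equal(predict_ln_solubility_coef(J_FIVE_TERM, w1, Tk, lx1, lx2),
               hand, tolerance = 1e-14)
})

test_that("back-calculation reproduces anchors exactly and covers all records", {
  cfg <- generator_config(seed = 4, noise_sigma = 0.05, grid_basis = "mole")
  conv <- convert_dataset(generate_dataset(cfg), 1)
  fit <- fit_ja(conv, np = 2)
  bc <- back_calculate(fit, conv)
  expect_equal(nrow(bc), conv$n)
  pure <- conv$data$w1 %in% c(0, 1)
  expect_equal(bc$x_cal[pure], bc$x_exp[pure], tolerance = 1e-12)
  expect_true(all(bc$x_cal > 0))
})

test_that("scale invariance: multiplying solubilities leaves J unchanged", {
  ds <- generate_dataset(generator_config(seed = 8, noise_sigma = 0.05,
                                          grid_basis = "mole"))
  k <- 0.37
  scaled <- ds
  scaled$records$solubility <- scaled$records$solubility * k
  f1 <- fit_ja(convert_dataset(ds, 1), 2)
  f2 <- fit_ja(convert_dataset(scaled, 1), 2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  b1 <- metrics_report(back_calculate(f1, convert_dataset(ds, 1)))
  b2 <- metrics_report(back_calculate(f2, convert_dataset(scaled, 1)))
  expect_equal(b1$mrd_percent, b2$mrd_percent, tolerance = 1e-9)
  expect_equal(b1$rmsd_log, b2$rmsd_log, tolerance = 1e-9)
  expect_equal(b1$e_log, b2$e_log, tolerance = 1e-9)
  expect_equal(b2$e_arith, k * b1$e_arith, tolerance = 1e-9)
  expect_equal(b2$rmsd_arith, k * b1$rmsd_arith, tolerance = 1e-9)
})

test_that("solvent-swap symmetry: J_i -> (-1)^i J_i", {
  ds <- generate_dataset(generator_config(seed = 12, noise_sigma = 0.05,
                                          grid_basis = "mole"))
  swapped <- solubility_dataset(
    label = ds$label, drug = ds$drug,
    solvent1 = ds$solvent2, solvent2 = ds$solvent1,
    records = transform(ds$records, w1 = 1 - w1),
    solvent_basis = ds$solvent_basis,
    solubility_unit = ds$solubility_unit
  )
  f <- fit_ja(convert_dataset(ds, 1), 2)
  fs <- fit_ja(convert_dataset(swapped, 1), 2)
  expect_equal(unname(fs$coefficients),
               unname(f$coefficients) * c(1, -1, 1), tolerance = 1e-8)
  # identical predictions at corresponding compositions
  conv <- convert_dataset(ds, 1)
  convs <- convert_dataset(swapped, 1)
  expect_equal(back_calculate(fs, convs)$x_cal,
               back_calculate(f, conv)$x_cal, tolerance = 1e-9)
})

test_that("nested fits never increase the residual sum of squares", {
  conv <- convert_dataset(
    generate_dataset(generator_config(seed = 21, noise_sigma = 0.08,
                                      grid_basis = "mole")), 1)
  rss <- vapply(0:4, function(np) fit_ja(conv, np)$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-12))
})

test_that("backward elimination drops only non-significant terms", {
  # truth has J3 = 0: pruning should remove it and keep the strong terms
  cfg <- generator_config(J_true = c(J_SD_ACN_MEOH, 0), noise_sigma = 0.05,
                          seed = 5, grid_basis = "mole")
  conv <- convert_dataset(generate_dataset(cfg), 1)
  fit <- fit_ja(conv, np = 3, prune = TRUE, alpha = 0.05)
  expect_equal(unname(fit$retained), c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(unname(fit$coefficients[4]), 0)
  expect_true(all(fit$p_values[fit$retained] <= 0.05))
  expect_true(is.na(fit$p_values[4]))
  # without pruning all terms are estimated
  fit_np <- fit_ja(conv, np = 3, prune = FALSE)
  expect_true(all(fit_np$retained))
})

test_that("fits serialise to JSON with all contract fields", {
  fit <- fit_ja(convert_dataset(make_tiny_dataset(), 4), np = 2)
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$np, 2)
  expect_equal(js$code, 4)
  expect_named(js$coefficients, c("J0", "J1", "J2"))
  expect_equal(js$n_regression_points, fit$n_regression_points)
})
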