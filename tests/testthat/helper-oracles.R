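# Independent oracles and fixture builders used across the suite.

# Brute-force normal-equations OLS, independent of the QR path in the
# implementation.
oracle_normal_equations <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Brute-force mole fraction -> molarity via an explicit mole/mass balance on
# one mole of saturated solution (independent derivation of the formula).
oracle_molefrac_to_molar <- function(x_d, x1_mole, Md, M1, M2, rho_sat) {
  n_d <- x_d
  n_1 <- (1 - x_d) * x1_mole
  n_2 <- (1 - x_d) * (1 - x1_mole)
  mass_g <- n_d * Md + n_1 * M1 + n_2 * M2
  volume_L <- mass_g / (1000 * rho_sat)
  n_d / volume_L
}

# A small hand-built dataset: 3 temperatures x 5 mass-basis compositions,
# mole-fraction solubilities on the ideal-mixing plane (all J = 0) so the
# numbers are easy to reason about.
make_tiny_dataset <- function(rho_sat = 1.0) {
  temps <- c(298.2, 308.2, 318.2)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  w1 <- rep(grid, times = length(temps))
  Tk <- rep(temps, each = length(grid))
  ln_x1 <- 2.0 - 2000 / Tk
  ln_x2 <- 3.0 - 3900 / Tk
  x <- exp(w1 * ln_x1 + (1 - w1) * ln_x2)
  solubility_dataset(
    label = "tiny", drug = drug_spec("tinydrug", 200),
    solvent1 = solvent_spec("ethanol", 46.07, 0.789),
    solvent2 = solvent_spec("water", 18.02, 0.997),
    records = data.frame(temperature = Tk, w1 = w1, solubility = x,
                         rho_sat = rho_sat),
    solvent_basis = "mass", solubility_unit = "mole_fraction"
  )
}

# Noise-free generator in a given unit code's own space.
make_code_space_config <- function(code, J_true = c(897.693, -1417.112,
                                                    1671.752), ...) {
  uc <- unit_code(code)
  generator_config(J_true = J_true, noise_sigma = 0,
                   grid_basis = uc$solvent_basis,
                   solute_unit = uc$solute_unit, ...)
}

metric_names <- c("mrd_percent", "rmsd_arith", "rmsd_log", "e_arith",
                  "e_log")

metric_values <- function(report) unlist(report[metric_names])
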