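# Synthetic saturation datasets with known ground truth.
#
# The generator evaluates the cosolvency model forward in a chosen unit-code
# space: mono-solvent log-solubilities follow a van't Hoff law
# ln x_pure(T) = A + B/T, mixed-composition log-solubilities follow the
# model with known J coefficients, and zero-mean Gaussian noise is added on
# the log scale (multiplicative log-normal on the solubility). Mono-solvent
# anchors are noise-free by default, since the model treats them as known
# inputs. A volume-additive mixture density times a weak drug-content
# coupling (1 + kappa * x_drug) supplies the saturated-solution density so
# that all nine unit codes are computable and exactly invertible.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a three-temperature, eleven-composition study of a
#' moderately soluble drug (M = 250 g/mol) in an ethanol/water-like binary
#' system, with the interaction coefficients of a real literature fit
#' (J = 897.693, -1417.112, 1671.752 K) and 5% multiplicative noise.
#'
#' @param J_true Numeric vector of true coefficients (J0, J1, ...), kelvin.
#' @param vant_hoff List with `solvent1 = c(A, B)` and `solvent2 = c(A, B)`
#'   giving `ln x_pure(T) = A + B/T` in the generated solute unit.
#' @param temperatures Temperatures in K.
#' @param grid Solute-free compositions of solvent 1; must include 0 and 1.
#' @param grid_basis Basis in which the grid (and the model) is expressed.
#' @param solute_unit Unit in which the model generates solubilities.
#' @param noise_sigma Standard deviation of the additive log-scale noise.
#' @param noisy_anchors If TRUE, the pure-solvent anchors also receive noise.
#' @param seed Integer RNG seed; identical configs give identical datasets.
#' @param drug A [drug_spec()].
#' @param solvent1,solvent2 [solvent_spec()] objects.
#' @param kappa Drug-content density coupling: `rho_sat = rho_mix * (1 +
#'   kappa * x_drug)`.
#' @param label Dataset label.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    J_true = c(897.693, -1417.112, 1671.752),
    vant_hoff = list(solvent1 = c(A = 2.0, B = -2000),
                     solvent2 = c(A = 3.0, B = -3900)),
    temperatures = c(298.2, 308.2, 318.2),
    grid = seq(0, 1, by = 0.1),
    grid_basis = "mass",
    solute_unit = "mole_fraction",
    noise_sigma = 0.05,
    noisy_anchors = FALSE,
    seed = 1L,
    drug = drug_spec("synthetic-drug", 250),
    solvent1 = solvent_spec("cosolvent", 46.07, 0.789),
    solvent2 = solvent_spec("water", 18.02, 0.997),
    kappa = 0.1,
    label = "synthetic") {
  grid_basis <- match.arg(grid_basis, SOLVENT_BASES)
  solute_unit <- match.arg(solute_unit, SOLUTE_UNITS)
  stopifnot(is.numeric(J_true), length(J_true) >= 1L, length(J_true) <= 5L,
            noise_sigma >= 0, all(temperatures > 0),
            all(grid >= 0 & grid <= 1))
  if (!any(grid <= .endpoint_tol) || !any(grid >= 1 - .endpoint_tol)) {
    stop("composition grid must include the endpoints 0 and 1",
         call. = FALSE)
  }
  structure(
    list(J_true = J_true, vant_hoff = vant_hoff,
         temperatures = temperatures, grid = grid, grid_basis = grid_basis,
         solute_unit = solute_unit, noise_sigma = noise_sigma,
         noisy_anchors = noisy_anchors, seed = as.integer(seed),
         drug = drug, solvent1 = solvent1, solvent2 = solvent2,
         kappa = kappa, label = label),
    class = "generator_config"
  )
}

#' Generate a synthetic solubility dataset
#'
#' @param config A [generator_config()].
#' @return A valid [solubility_dataset()] whose mixed-composition records
#'   satisfy the model with `config$J_true` (exactly when `noise_sigma = 0`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  M1 <- config$solvent1$molar_mass
  M2 <- config$solvent2$molar_mass
  rho1 <- config$solvent1$pure_density
  rho2 <- config$solvent2$pure_density
  Md <- config$drug$molar_mass
  A1 <- config$vant_hoff$solvent1[1]; B1 <- config$vant_hoff$solvent1[2]
  A2 <- config$vant_hoff$solvent2[1]; B2 <- config$vant_hoff$solvent2[2]

  grid <- config$grid
  temps <- config$temperatures
  w1 <- rep(grid, times = length(temps))
  Tk <- rep(temps, each = length(grid))
  ln_x1 <- A1 + B1 / Tk
  ln_x2 <- A2 + B2 / Tk
  ln_xm <- predict_ln_solubility_coef(config$J_true, w1, Tk, ln_x1, ln_x2)

  mixed <- w1 > .endpoint_tol & w1 < 1 - .endpoint_tol
  noisy <- if (config$noisy_anchors) rep(TRUE, length(w1)) else mixed
  if (config$noise_sigma > 0) {
    ln_xm[noisy] <- ln_xm[noisy] +
      stats::rnorm(sum(noisy), 0, config$noise_sigma)
  }
  value <- exp(ln_xm)

  # saturated-solution density from the volume-additive mixture density and
  # a weak coupling to drug content (proxy mole fraction for volumetric
  # solute units; the conversions use the stored density, so round trips
  # remain exact regardless of the proxy)
  w_mass <- .convert_basis(w1, config$grid_basis, "mass", M1, M2, rho1, rho2)
  x1_mole <- .convert_basis(w1, config$grid_basis, "mole", M1, M2, rho1, rho2)
  rho_mix <- 1 / (w_mass / rho1 + (1 - w_mass) / rho2)
  Ms <- x1_mole * M1 + (1 - x1_mole) * M2
  x_d_proxy <- switch(config$solute_unit,
    mole_fraction = value,
    molar = value * Ms / (1000 * rho_mix),
    gram_per_liter = (value / Md) * Ms / (1000 * rho_mix)
  )
  rho_sat <- rho_mix * (1 + config$kappa * x_d_proxy)

  solubility_dataset(
    label = config$label, drug = config$drug,
    solvent1 = config$solvent1, solvent2 = config$solvent2,
    records = data.frame(temperature = Tk, w1 = w1, solubility = value,
                         rho_sat = rho_sat),
    solvent_basis = config$grid_basis,
    solubility_unit = config$solute_unit
  )
}

#' Multiply one record's solubility by a factor
#'
#' Produces an otherwise identical dataset with a single altered datum, the
#' device used to probe how the error criteria react to an outlier. The
#' result is not re-validated: a large factor can push a mole-fraction
#' solubility past 1, exactly as the manual alterations reported in the
#' source experiments do.
#'
#' @param dataset A [solubility_dataset()].
#' @param index Record index to perturb.
#' @param factor Positive multiplier.
#' @return The perturbed dataset.
#' @export
inject_outlier <- function(dataset, index, factor) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  index <- as.integer(index)
  if (index < 1L || index > nrow(dataset$records)) {
    stop("record index out of range", call. = FALSE)
  }
  if (!is.finite(factor) || factor <= 0) {
    stop("factor must be positive", call. = FALSE)
  }
  dataset$records$solubility[index] <-
    dataset$records$solubility[index] * factor
  dataset
}

#' Generate a suite of study-like synthetic datasets
#'
#' Emulates a literature collection: each dataset draws its interaction
#' coefficients, noise level, drug molar mass and van't Hoff anchors from
#' configurable ranges, on a mass-uniform composition grid.
#'
#' Presets:
#' * `"default"` - ethanol/water-like solvents (molar masses 46.07/18.02
#'   g/mol, densities 0.789/0.997 g/mL).
#' * `"wide-magnitude"` - pure-solvent solubilities stratified across many
#'   orders of magnitude, so molar solubilities across the suite span a
#'   ratio of at least 1e6 (as the extremes of real collections do).
#' * `"skewed"` - heavy cosolvent (molar-mass ratio 78.13/18.02) with equal
#'   solvent densities, so a mass-uniform grid maps to a strongly
#'   sub-0.5-mean mole-fraction grid while mass and volume means stay 0.5.
#'
#' @param n_datasets Number of datasets (>= 1).
#' @param seed Master RNG seed; the suite is fully reproducible.
#' @param preset One of `"default"`, `"wide-magnitude"`, `"skewed"`.
#' @param J_ranges List of `c(min, max)` ranges for J0, J1, J2.
#' @param noise_range Range for the log-scale noise SD.
#' @param grid Mass-basis composition grid.
#' @param temperatures Temperatures in K.
#' @return List of [solubility_dataset()] objects.
#' @export
make_paper_like_suite <- function(
    n_datasets, seed = 1L,
    preset = c("default", "wide-magnitude", "skewed"),
    J_ranges = list(J0 = c(-500, 1500), J1 = c(-1500, 1500),
                    J2 = c(-1000, 2000)),
    noise_range = c(0.02, 0.08),
    grid = seq(0, 1, by = 0.1),
    temperatures = c(298.2, 308.2, 318.2)) {
  preset <- match.arg(preset)
  stopifnot(n_datasets >= 1L)
  set.seed(as.integer(seed))
  if (preset == "skewed") {
    solv1 <- solvent_spec("heavy-cosolvent", 78.13, 0.997)
    solv2 <- solvent_spec("water", 18.02, 0.997)
  } else {
    solv1 <- solvent_spec("cosolvent", 46.07, 0.789)
    solv2 <- solvent_spec("water", 18.02, 0.997)
  }
  dataset_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
  lapply(seq_len(n_datasets), function(k) {
    J <- vapply(J_ranges, function(rg) stats::runif(1, rg[1], rg[2]),
                numeric(1))
    sigma <- stats::runif(1, noise_range[1], noise_range[2])
    Md <- stats::runif(1, 150, 500)
    if (preset == "wide-magnitude") {
      # stratified log-solubility levels guarantee the suite spans the range
      lo <- log(1e-7); hi <- log(0.3)
      frac <- if (n_datasets == 1L) 0.5 else (k - 1) / (n_datasets - 1)
      lnx1_298 <- lo + frac * (hi - lo)
      lnx2_298 <- lnx1_298 - stats::runif(1, 0.5, 2.5)
    } else {
      lnx1_298 <- stats::runif(1, log(1e-3), log(0.1))
      lnx2_298 <- stats::runif(1, log(1e-6), log(1e-2))
    }
    B1 <- stats::runif(1, -4000, -1000)
    B2 <- stats::runif(1, -4000, -1000)
    cfg <- generator_config(
      J_true = unname(J),
      vant_hoff = list(solvent1 = c(A = lnx1_298 - B1 / 298.2, B = B1),
                       solvent2 = c(A = lnx2_298 - B2 / 298.2, B = B2)),
      temperatures = temperatures, grid = grid, grid_basis = "mass",
      noise_sigma = sigma, seed = dataset_seeds[k],
      drug = drug_spec(paste0("drug-", (k - 1) %% max(1, n_datasets %/% 2) + 1),
                       Md),
      solvent1 = solv1, solvent2 = solv2,
      label = sprintf("SN-%02d", k)
    )
    generate_dataset(cfg)
  })
}
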