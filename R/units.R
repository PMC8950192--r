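# Exact algebraic conversions between solvent-composition bases and solute
# concentration units. All functions are vectorised and carried out in
# double precision; nothing is rounded before serialisation.

#' Solvent composition: mole fraction to mass fraction
#'
#' `w = x1 M1 / (x1 M1 + (1 - x1) M2)` on the solute-free mixture.
#'
#' @param x1 Mole fraction of solvent 1 in \[0, 1\].
#' @param M1,M2 Solvent molar masses (g/mol).
#' @return Mass fraction of solvent 1.
#' @export
solvent_mole_to_mass <- function(x1, M1, M2) {
  stopifnot(all(M1 > 0), all(M2 > 0))
  x1 * M1 / (x1 * M1 + (1 - x1) * M2)
}

#' Solvent composition: mass fraction to mole fraction
#'
#' Exact inverse of [solvent_mole_to_mass()].
#'
#' @param w1 Mass fraction of solvent 1 in \[0, 1\].
#' @param M1,M2 Solvent molar masses (g/mol).
#' @return Mole fraction of solvent 1.
#' @export
solvent_mass_to_mole <- function(w1, M1, M2) {
  stopifnot(all(M1 > 0), all(M2 > 0))
  (w1 / M1) / (w1 / M1 + (1 - w1) / M2)
}

#' Solvent composition: mass fraction to volume fraction
#'
#' Volume-additive (ideal-mixing) convention from pure-solvent densities:
#' `v = (w1/rho1) / (w1/rho1 + (1 - w1)/rho2)`.
#'
#' @param w1 Mass fraction of solvent 1.
#' @param rho1,rho2 Pure-solvent densities (g/mL).
#' @return Volume fraction of solvent 1.
#' @export
solvent_mass_to_volume <- function(w1, rho1, rho2) {
  stopifnot(all(rho1 > 0), all(rho2 > 0))
  (w1 / rho1) / (w1 / rho1 + (1 - w1) / rho2)
}

#' Solvent composition: volume fraction to mass fraction
#'
#' Exact inverse of [solvent_mass_to_volume()].
#'
#' @param v1 Volume fraction of solvent 1.
#' @param rho1,rho2 Pure-solvent densities (g/mL).
#' @return Mass fraction of solvent 1.
#' @export
solvent_volume_to_mass <- function(v1, rho1, rho2) {
  stopifnot(all(rho1 > 0), all(rho2 > 0))
  v1 * rho1 / (v1 * rho1 + (1 - v1) * rho2)
}

# Composition in any basis -> any other basis, routed through mass.
.convert_basis <- function(value, from, to, M1, M2, rho1, rho2) {
  if (from == to) return(value)
  w_mass <- switch(from,
    mole = solvent_mole_to_mass(value, M1, M2),
    mass = value,
    volume = solvent_volume_to_mass(value, rho1, rho2)
  )
  switch(to,
    mole = solvent_mass_to_mole(w_mass, M1, M2),
    mass = w_mass,
    volume = solvent_mass_to_volume(w_mass, rho1, rho2)
  )
}

#' Solute concentration: mole fraction to molarity
#'
#' For a saturated solution with drug mole fraction `x_d` and solute-free
#' solvent-1 mole fraction `x1_mole` the ternary mole fractions are
#' `x1s = (1 - x_d) x1_mole` and `x2s = (1 - x_d)(1 - x1_mole)`, the mean
#' molar mass is `Mbar = x_d Md + x1s M1 + x2s M2` (g/mol), and
#' `C = 1000 x_d rho_sat / Mbar` (mol/L).
#'
#' @param x_d Drug mole fraction in (0, 1).
#' @param x1_mole Solute-free mole fraction of solvent 1.
#' @param Md,M1,M2 Molar masses (g/mol) of drug and solvents.
#' @param rho_sat Saturated-solution density (g/mL).
#' @return Molarity in mol/L.
#' @export
solute_molefrac_to_molar <- function(x_d, x1_mole, Md, M1, M2, rho_sat) {
  if (any(is.na(rho_sat))) {
    stop("saturated-solution density is required for molar conversions",
         call. = FALSE)
  }
  Mbar <- x_d * Md + (1 - x_d) * (x1_mole * M1 + (1 - x1_mole) * M2)
  1000 * x_d * rho_sat / Mbar
}

#' Solute concentration: molarity to mole fraction
#'
#' Exact inverse of [solute_molefrac_to_molar()]:
#' `x_d = C Ms / (1000 rho_sat - C (Md - Ms))` with
#' `Ms = x1_mole M1 + (1 - x1_mole) M2` the solute-free mean solvent molar
#' mass.
#'
#' @inheritParams solute_molefrac_to_molar
#' @param C Molarity (mol/L).
#' @return Drug mole fraction.
#' @export
solute_molar_to_molefrac <- function(C, x1_mole, Md, M1, M2, rho_sat) {
  if (any(is.na(rho_sat))) {
    stop("saturated-solution density is required for molar conversions",
         call. = FALSE)
  }
  Ms <- x1_mole * M1 + (1 - x1_mole) * M2
  C * Ms / (1000 * rho_sat - C * (Md - Ms))
}

#' Solute concentration: molarity to grams per liter
#'
#' @param C Molarity (mol/L).
#' @param Md Drug molar mass (g/mol).
#' @return Concentration in g/L, exactly `C * Md`.
#' @export
molar_to_gram_per_liter <- function(C, Md) {
  stopifnot(all(C >= 0), Md > 0)
  C * Md
}

#' Solute concentration: grams per liter to molarity
#'
#' @param S Concentration in g/L.
#' @param Md Drug molar mass (g/mol).
#' @return Molarity, exactly `S / Md`.
#' @export
gram_per_liter_to_molar <- function(S, Md) {
  stopifnot(all(S >= 0), Md > 0)
  S / Md
}

# Solute concentration in the dataset's native unit -> drug mole fraction.
# x1_mole is the solute-free mole-basis composition of each record.
.solute_to_molefrac <- function(value, unit, x1_mole, Md, M1, M2, rho_sat) {
  switch(unit,
    mole_fraction = value,
    molar = solute_molar_to_molefrac(value, x1_mole, Md, M1, M2, rho_sat),
    gram_per_liter = solute_molar_to_molefrac(
      gram_per_liter_to_molar(value, Md), x1_mole, Md, M1, M2, rho_sat)
  )
}

.solute_from_molefrac <- function(x_d, unit, x1_mole, Md, M1, M2, rho_sat) {
  switch(unit,
    mole_fraction = x_d,
    molar = solute_molefrac_to_molar(x_d, x1_mole, Md, M1, M2, rho_sat),
    gram_per_liter = molar_to_gram_per_liter(
      solute_molefrac_to_molar(x_d, x1_mole, Md, M1, M2, rho_sat), Md)
  )
}

#' Convert a dataset to one of the nine unit codes
#'
#' Re-expresses every record's solvent composition in the code's basis and
#' its solubility in the code's solute unit, and attaches the converted
#' mono-solvent anchor solubilities (`x1T`, `x2T`) at each record's
#' temperature. Volumetric solute units (molar, g/L) require a
#' saturated-solution density per record; if absent it is defaulted from the
#' dataset's mixture density table when available, otherwise conversion
#' fails listing the offending records.
#'
#' @param dataset A valid [solubility_dataset()].
#' @param code A [unit_code()] or integer 1-9.
#' @return An object of class `converted_dataset` with a `data` data.frame
#'   (`T`, `w1`, `xm`, `x1T`, `x2T`) aligned with the source records.
#' @export
convert_dataset <- function(dataset, code) {
  validate_dataset(dataset)
  code <- unit_code(code)
  r <- dataset$records
  Md <- dataset$drug$molar_mass
  M1 <- dataset$solvent1$molar_mass
  M2 <- dataset$solvent2$molar_mass
  rho1 <- dataset$solvent1$pure_density
  rho2 <- dataset$solvent2$pure_density

  # solute-free compositions in mole and mass bases (needed regardless of
  # target) and in the target basis
  x1_mole <- .convert_basis(r$w1, dataset$solvent_basis, "mole",
                            M1, M2, rho1, rho2)
  w1_mass <- .convert_basis(r$w1, dataset$solvent_basis, "mass",
                            M1, M2, rho1, rho2)
  w1_target <- .convert_basis(r$w1, dataset$solvent_basis, code$solvent_basis,
                              M1, M2, rho1, rho2)

  rho_sat <- r$rho_sat
  needs_rho <- dataset$solubility_unit != "mole_fraction" ||
    code$solute_unit != "mole_fraction"
  if (needs_rho && any(is.na(rho_sat))) {
    fallback <- .mixture_density_lookup(dataset, r$temperature, w1_mass)
    rho_sat[is.na(rho_sat)] <- fallback[is.na(rho_sat)]
    if (any(is.na(rho_sat))) {
      stop("code ", code$code, " needs a saturated-solution density; ",
           "missing at record(s) ", paste(which(is.na(rho_sat)),
           collapse = ", "), call. = FALSE)
    }
  }

  x_d <- .solute_to_molefrac(r$solubility, dataset$solubility_unit,
                             x1_mole, Md, M1, M2, rho_sat)
  if (any(!is.finite(x_d) | x_d <= 0 | x_d >= 1)) {
    stop("conversion produced drug mole fractions outside (0, 1) at ",
         "record(s) ", paste(which(!is.finite(x_d) | x_d <= 0 | x_d >= 1),
         collapse = ", "), call. = FALSE)
  }
  xm <- .solute_from_molefrac(x_d, code$solute_unit, x1_mole, Md, M1, M2,
                              rho_sat)

  # anchor solubilities per temperature, in the target solute unit
  x1T <- rep(NA_real_, nrow(r))
  x2T <- rep(NA_real_, nrow(r))
  for (Tk in unique_temperatures(dataset)) {
    at_T <- abs(r$temperature - Tk) <= .temp_tol * Tk
    i1 <- which(at_T & r$w1 >= 1 - .endpoint_tol)[1L]
    i2 <- which(at_T & r$w1 <= .endpoint_tol)[1L]
    x1T[at_T] <- xm[i1]
    x2T[at_T] <- xm[i2]
  }

  structure(
    list(
      source_label = dataset$label,
      drug = dataset$drug,
      code = code,
      data = data.frame(T = r$temperature, w1 = w1_target, xm = xm,
                        x1T = x1T, x2T = x2T),
      n = nrow(r)
    ),
    class = "converted_dataset"
  )
}

#' @export
print.converted_dataset <- function(x, ...) {
  cat("<converted_dataset> '", x$source_label, "' as code ", x$code$code,
      " (", x$code$solvent_basis, " basis, ", x$code$solute_unit, ")\n",
      "  ", x$n, " records, T: ",
      paste(format(sort(unique(x$data$T))), collapse = ", "), " K\n",
      sep = "")
  invisible(x)
}
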