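#' @keywords internal
"_PACKAGE"

# Controlled vocabularies for the dataset schema.
SOLVENT_BASES <- c("mole", "mass", "volume")
SOLUTE_UNITS <- c("mole_fraction", "molar", "gram_per_liter")

# Tolerance for recognising mono-solvent endpoints and matching temperatures.
.endpoint_tol <- 1e-12
.temp_tol <- 1e-9

#' Describe a drug (the solute)
#'
#' @param name Drug name (free text).
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @return An object of class `drug_spec`.
#' @export
drug_spec <- function(name, molar_mass) {
  stopifnot(is.character(name), length(name) == 1L)
  molar_mass <- as.numeric(molar_mass)
  if (!is.finite(molar_mass) || molar_mass <= 0) {
    stop("drug molar_mass must be a positive finite number", call. = FALSE)
  }
  structure(list(name = name, molar_mass = molar_mass), class = "drug_spec")
}

#' Describe a solvent
#'
#' @param name Solvent name (free text).
#' @param molar_mass Molar mass in g/mol; positive.
#' @param pure_density Pure-solvent density in g/mL; positive. Used for the
#'   volume-additive composition conversions and the mixture density model.
#' @param density_ref_temperature Optional reference temperature (K) of the
#'   density value, kept as metadata only.
#' @return An object of class `solvent_spec`.
#' @export
solvent_spec <- function(name, molar_mass, pure_density,
                         density_ref_temperature = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  molar_mass <- as.numeric(molar_mass)
  pure_density <- as.numeric(pure_density)
  if (!is.finite(molar_mass) || molar_mass <= 0) {
    stop("solvent molar_mass must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(pure_density) || pure_density <= 0) {
    stop("solvent pure_density must be a positive finite number", call. = FALSE)
  }
  structure(
    list(name = name, molar_mass = molar_mass, pure_density = pure_density,
         density_ref_temperature = as.numeric(density_ref_temperature)),
    class = "solvent_spec"
  )
}

#' Assemble a solubility dataset
#'
#' A dataset holds saturation measurements of one drug in one binary solvent
#' system. Each record carries a temperature (K), the solute-free composition
#' of solvent 1 (`w1`, in the dataset's `solvent_basis`), the saturated
#' solubility in the dataset's `solubility_unit`, and optionally the density
#' of the saturated solution (g/mL). The composition of solvent 2 is never
#' stored; it is always `1 - w1`.
#'
#' Validation enforces: at least 5 records; positive temperatures and
#' solubilities; `w1` in \[0, 1\]; mole-fraction solubilities below 1; and, for
#' every distinct temperature, the presence of both mono-solvent anchor
#' records (`w1 = 0` and `w1 = 1`), which supply the pure-solvent
#' solubilities the model treats as known.
#'
#' @param label Free-text dataset label.
#' @param drug A [drug_spec()].
#' @param solvent1,solvent2 [solvent_spec()] objects.
#' @param records A data.frame with columns `temperature`, `w1`, `solubility`
#'   and optionally `rho_sat` (NA allowed).
#' @param solvent_basis One of `"mole"`, `"mass"`, `"volume"`: the basis in
#'   which `w1` is expressed (solute-free).
#' @param solubility_unit One of `"mole_fraction"`, `"molar"`,
#'   `"gram_per_liter"`.
#' @param mixture_density_table Optional data.frame (`temperature`, `w1_mass`,
#'   `rho`) of solute-free mixture densities, used only to default a missing
#'   saturated-solution density.
#' @param validate If TRUE (default), run [validate_dataset()].
#' @return An object of class `solubility_dataset`.
#' @export
solubility_dataset <- function(label, drug, solvent1, solvent2, records,
                               solvent_basis, solubility_unit,
                               mixture_density_table = NULL,
                               validate = TRUE) {
  stopifnot(inherits(drug, "drug_spec"),
            inherits(solvent1, "solvent_spec"),
            inherits(solvent2, "solvent_spec"),
            is.data.frame(records))
  solvent_basis <- match.arg(solvent_basis, SOLVENT_BASES)
  solubility_unit <- match.arg(solubility_unit, SOLUTE_UNITS)
  if (is.null(records$rho_sat)) records$rho_sat <- NA_real_
  records <- data.frame(
    temperature = as.numeric(records$temperature),
    w1 = as.numeric(records$w1),
    solubility = as.numeric(records$solubility),
    rho_sat = as.numeric(records$rho_sat)
  )
  ds <- structure(
    list(label = as.character(label), drug = drug,
         solvent1 = solvent1, solvent2 = solvent2,
         solvent_basis = solvent_basis, solubility_unit = solubility_unit,
         records = records, mixture_density_table = mixture_density_table),
    class = "solubility_dataset"
  )
  if (validate) validate_dataset(ds)
  ds
}

#' Validate a solubility dataset
#'
#' Checks every schema invariant and stops with an informative error on the
#' first violation. Returns the dataset invisibly on success.
#'
#' @param dataset A `solubility_dataset`.
#' @return The dataset, invisibly.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  r <- dataset$records
  if (nrow(r) < 5L) {
    stop("dataset '", dataset$label, "' has ", nrow(r),
         " records; at least 5 are required", call. = FALSE)
  }
  bad <- which(!is.finite(r$temperature) | r$temperature <= 0)
  if (length(bad)) {
    stop("non-positive temperature at record(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(r$w1) | r$w1 < 0 | r$w1 > 1)
  if (length(bad)) {
    stop("w1 outside [0, 1] at record(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(r$solubility) | r$solubility <= 0)
  if (length(bad)) {
    stop("non-positive solubility at record(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (dataset$solubility_unit == "mole_fraction") {
    bad <- which(r$solubility >= 1)
    if (length(bad)) {
      stop("mole-fraction solubility >= 1 at record(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  bad <- which(!is.na(r$rho_sat) & r$rho_sat <= 0)
  if (length(bad)) {
    stop("non-positive saturated density at record(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (Tk in unique_temperatures(dataset)) {
    at_T <- abs(r$temperature - Tk) <= .temp_tol * Tk
    if (!any(at_T & r$w1 <= .endpoint_tol)) {
      stop("missing mono-solvent anchor w1 = 0 at T = ", format(Tk), " K",
           call. = FALSE)
    }
    if (!any(at_T & r$w1 >= 1 - .endpoint_tol)) {
      stop("missing mono-solvent anchor w1 = 1 at T = ", format(Tk), " K",
           call. = FALSE)
    }
  }
  invisible(dataset)
}

#' Distinct temperatures of a dataset
#'
#' @param dataset A `solubility_dataset`.
#' @return Sorted numeric vector of distinct temperatures (K).
#' @export
unique_temperatures <- function(dataset) {
  sort(unique(dataset$records$temperature))
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat("<solubility_dataset> '", x$label, "'\n", sep = "")
  cat("  drug:    ", x$drug$name, " (M = ", x$drug$molar_mass, " g/mol)\n",
      sep = "")
  cat("  solvents:", x$solvent1$name, "+", x$solvent2$name, "\n")
  cat("  records: ", nrow(x$records), " (", x$solvent_basis, "-basis w1, ",
      x$solubility_unit, " solubility)\n", sep = "")
  cat("  T (K):   ", paste(format(unique_temperatures(x)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.drug_spec <- function(x, ...) {
  cat("<drug_spec>", x$name, "M =", x$molar_mass, "g/mol\n")
  invisible(x)
}

#' @export
print.solvent_spec <- function(x, ...) {
  cat("<solvent_spec>", x$name, "M =", x$molar_mass, "g/mol, rho =",
      x$pure_density, "g/mL\n")
  invisible(x)
}

# Interpolate a solute-free mixture density from the optional table at a
# record's temperature and mass-basis composition. Returns NA when no table
# or the temperature is absent.
.mixture_density_lookup <- function(dataset, temperature, w1_mass) {
  tab <- dataset$mixture_density_table
  if (is.null(tab)) return(rep(NA_real_, length(w1_mass)))
  out <- rep(NA_real_, length(w1_mass))
  for (i in seq_along(w1_mass)) {
    at_T <- abs(tab$temperature - temperature[i]) <=
      .temp_tol * temperature[i]
    if (sum(at_T) >= 2L) {
      out[i] <- stats::approx(tab$w1_mass[at_T], tab$rho[at_T],
                              xout = w1_mass[i], rule = 2)$y
    }
  }
  out
}
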