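# Reading and writing datasets.
#
# Two on-disk forms are supported:
#  * JSON: one object with drug/solvent specs and a `records` array.
#  * CSV: one record per row with a single `#meta ` comment line on top
#    holding the drug/solvent specs as JSON.
# Numeric values are serialised with 15 significant digits so that a
# write/read round trip is the identity to at least 12 significant digits.

.spec_to_list <- function(dataset) {
  out <- list(
    label = dataset$label,
    drug = list(name = dataset$drug$name,
                molar_mass_g_per_mol = dataset$drug$molar_mass),
    solvent1 = list(name = dataset$solvent1$name,
                    molar_mass_g_per_mol = dataset$solvent1$molar_mass,
                    pure_density_g_per_mL = dataset$solvent1$pure_density),
    solvent2 = list(name = dataset$solvent2$name,
                    molar_mass_g_per_mol = dataset$solvent2$molar_mass,
                    pure_density_g_per_mL = dataset$solvent2$pure_density),
    solvent_basis = dataset$solvent_basis,
    solubility_unit = dataset$solubility_unit
  )
  if (!is.null(dataset$mixture_density_table)) {
    out$mixture_density_table <- dataset$mixture_density_table
  }
  out
}

.specs_from_list <- function(meta) {
  need <- c("label", "drug", "solvent1", "solvent2")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("dataset metadata is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  list(
    label = meta$label,
    drug = drug_spec(meta$drug$name, meta$drug$molar_mass_g_per_mol),
    solvent1 = solvent_spec(meta$solvent1$name,
                            meta$solvent1$molar_mass_g_per_mol,
                            meta$solvent1$pure_density_g_per_mL),
    solvent2 = solvent_spec(meta$solvent2$name,
                            meta$solvent2$molar_mass_g_per_mol,
                            meta$solvent2$pure_density_g_per_mL),
    mixture_density_table =
      if (is.null(meta$mixture_density_table)) NULL
      else as.data.frame(meta$mixture_density_table)
  )
}

.check_unit_strings <- function(basis, unit) {
  if (!basis %in% SOLVENT_BASES) {
    stop("unknown solvent_basis '", basis, "'; expected one of ",
         paste(SOLVENT_BASES, collapse = ", "), call. = FALSE)
  }
  if (!unit %in% SOLUTE_UNITS) {
    stop("unknown solubility_unit '", unit, "'; expected one of ",
         paste(SOLUTE_UNITS, collapse = ", "), call. = FALSE)
  }
}

#' Read a solubility dataset from disk
#'
#' The CSV form has record columns `T_K` (or `T_C`, converted on ingest via
#' T_K = T_C + 273.15), `w1`, `solvent_basis`, `solubility`,
#' `solubility_unit` and optional `rho_sat_g_per_mL` (blank allowed), plus a
#' leading `#meta {...}` line with the drug/solvent specifications. The JSON
#' form mirrors this with a `records` array. The returned dataset is fully
#' validated.
#'
#' @param path File to read.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return A [solubility_dataset()].
#' @export
read_dataset <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") .read_dataset_json(path) else .read_dataset_csv(path)
}

.read_dataset_json <- function(path) {
  meta <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  specs <- .specs_from_list(meta)
  .check_unit_strings(meta$solvent_basis, meta$solubility_unit)
  rec <- as.data.frame(meta$records)
  records <- .records_from_table(rec)
  solubility_dataset(
    label = specs$label, drug = specs$drug,
    solvent1 = specs$solvent1, solvent2 = specs$solvent2,
    records = records,
    solvent_basis = meta$solvent_basis,
    solubility_unit = meta$solubility_unit,
    mixture_density_table = specs$mixture_density_table
  )
}

.read_dataset_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_line <- grep("^#meta ", lines, value = TRUE)
  if (length(meta_line) != 1L) {
    stop("CSV dataset must contain exactly one '#meta {...}' header line",
         call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sub("^#meta ", "", meta_line),
                             simplifyVector = TRUE)
  specs <- .specs_from_list(meta)
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  basis <- unique(tab$solvent_basis)
  unit <- unique(tab$solubility_unit)
  if (length(basis) != 1L || length(unit) != 1L) {
    stop("all records must share one solvent_basis and one solubility_unit",
         call. = FALSE)
  }
  .check_unit_strings(basis, unit)
  records <- .records_from_table(tab)
  solubility_dataset(
    label = specs$label, drug = specs$drug,
    solvent1 = specs$solvent1, solvent2 = specs$solvent2,
    records = records, solvent_basis = basis, solubility_unit = unit,
    mixture_density_table = specs$mixture_density_table
  )
}

.records_from_table <- function(tab) {
  if (!is.null(tab$T_K)) {
    temperature <- as.numeric(tab$T_K)
  } else if (!is.null(tab$T_C)) {
    temperature <- as.numeric(tab$T_C) + 273.15
  } else {
    stop("records need a temperature column 'T_K' (or 'T_C')", call. = FALSE)
  }
  rho <- if (is.null(tab$rho_sat_g_per_mL)) NA_real_ else
    as.numeric(tab$rho_sat_g_per_mL)
  data.frame(temperature = temperature, w1 = as.numeric(tab$w1),
             solubility = as.numeric(tab$solubility), rho_sat = rho)
}

#' Write a solubility dataset to disk
#'
#' Emits a file that [read_dataset()] reads back to an equal dataset (values
#' preserved to at least 12 significant digits). A missing saturated density
#' is serialised as blank (CSV) or `null` (JSON).
#'
#' @param dataset A valid [solubility_dataset()].
#' @param path Output path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  validate_dataset(dataset)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- .spec_to_list(dataset)
    r <- dataset$records
    obj$records <- data.frame(T_K = r$temperature, w1 = r$w1,
                              solubility = r$solubility,
                              rho_sat_g_per_mL = r$rho_sat)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    meta <- jsonlite::toJSON(.spec_to_list(dataset), auto_unbox = TRUE,
                             digits = NA)
    r <- dataset$records
    fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15))
    tab <- data.frame(
      T_K = fmt(r$temperature), w1 = fmt(r$w1),
      solvent_basis = dataset$solvent_basis,
      solubility = fmt(r$solubility),
      solubility_unit = dataset$solubility_unit,
      rho_sat_g_per_mL = fmt(r$rho_sat)
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#meta ", meta), con)
    utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
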