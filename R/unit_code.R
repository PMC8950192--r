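#' Numerical-analysis unit codes 1-9
#'
#' Each code pairs a solute concentration unit with a solute-free
#' solvent-composition basis:
#'
#' | basis \\ solute unit | mole fraction | molar | gram/liter |
#' |---------------------|---------------|-------|------------|
#' | mole fraction       | 1             | 2     | 3          |
#' | mass fraction       | 4             | 5     | 6          |
#' | volume fraction     | 7             | 8     | 9          |
#'
#' @param code Integer 1-9.
#' @return An object of class `unit_code` with fields `code`,
#'   `solvent_basis` and `solute_unit`.
#' @export
unit_code <- function(code) {
  if (inherits(code, "unit_code")) return(code)
  code <- as.integer(code)
  if (length(code) != 1L || is.na(code) || code < 1L || code > 9L) {
    stop("unit code must be a single integer in 1..9", call. = FALSE)
  }
  basis <- SOLVENT_BASES[(code - 1L) %/% 3L + 1L]
  unit <- SOLUTE_UNITS[(code - 1L) %% 3L + 1L]
  structure(list(code = code, solvent_basis = basis, solute_unit = unit),
            class = "unit_code")
}

#' @export
print.unit_code <- function(x, ...) {
  cat("<unit_code ", x$code, "> solvent basis: ", x$solvent_basis,
      ", solute unit: ", x$solute_unit, "\n", sep = "")
  invisible(x)
}
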