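# Five accuracy criteria comparing back-calculated with experimental
# solubilities. The relative and arithmetic mean deviations are defined
# with absolute values: the criteria are deviations, and a signed mean
# would cancel to zero for any bias-free fit.

.bc_vectors <- function(bc) {
  if (inherits(bc, "back_calculation") ||
      (is.data.frame(bc) && all(c("x_exp", "x_cal") %in% names(bc)))) {
    list(x_exp = bc$x_exp, x_cal = bc$x_cal)
  } else {
    stop("expected a back_calculation (data.frame with x_exp, x_cal)",
         call. = FALSE)
  }
}

.check_nonempty <- function(v) {
  if (length(v$x_exp) == 0L) stop("empty back-calculation", call. = FALSE)
  if (any(v$x_exp <= 0)) {
    stop("experimental solubilities must be positive", call. = FALSE)
  }
}

#' Percentage mean relative deviation (MRD%)
#'
#' `(100/N) * sum(|x_cal - x_exp| / x_exp)`. Scale-invariant: unchanged
#' when both vectors are multiplied by the same positive constant.
#'
#' @param bc A [back_calculate()] result.
#' @return MRD in percent.
#' @export
mrd_percent <- function(bc) {
  v <- .bc_vectors(bc); .check_nonempty(v)
  100 * mean(abs(v$x_cal - v$x_exp) / v$x_exp)
}

#' Root-mean-square deviation, arithmetic scale (RMSD1)
#'
#' `sqrt(sum((x_cal - x_exp)^2) / N)`, in the solubility unit of the data.
#'
#' @inheritParams mrd_percent
#' @return RMSD1 in solubility units.
#' @export
rmsd_arith <- function(bc) {
  v <- .bc_vectors(bc); .check_nonempty(v)
  sqrt(mean((v$x_cal - v$x_exp)^2))
}

#' Root-mean-square deviation, logarithmic scale (RMSD2)
#'
#' `sqrt(sum((ln x_cal - ln x_exp)^2) / N)`; dimensionless and
#' scale-invariant.
#'
#' @inheritParams mrd_percent
#' @return RMSD2 (dimensionless).
#' @export
rmsd_log <- function(bc) {
  v <- .bc_vectors(bc); .check_nonempty(v)
  if (any(v$x_cal <= 0)) stop("back-calculated solubilities must be positive",
                              call. = FALSE)
  sqrt(mean((log(v$x_cal) - log(v$x_exp))^2))
}

#' Mean absolute error, arithmetic scale (E1)
#'
#' `sum(|x_cal - x_exp|) / N`, in the solubility unit of the data; scales
#' exactly with the unit (e.g. the g/L value is the molar value times the
#' drug molar mass).
#'
#' @inheritParams mrd_percent
#' @return E1 in solubility units.
#' @export
e_arith <- function(bc) {
  v <- .bc_vectors(bc); .check_nonempty(v)
  mean(abs(v$x_cal - v$x_exp))
}

#' Mean absolute error, logarithmic scale (E2)
#'
#' `sum(|ln x_cal - ln x_exp|) / N`; dimensionless and scale-invariant.
#'
#' @inheritParams mrd_percent
#' @return E2 (dimensionless).
#' @export
e_log <- function(bc) {
  v <- .bc_vectors(bc); .check_nonempty(v)
  if (any(v$x_cal <= 0)) stop("back-calculated solubilities must be positive",
                              call. = FALSE)
  mean(abs(log(v$x_cal) - log(v$x_exp)))
}

#' Compute all five error criteria
#'
#' @inheritParams mrd_percent
#' @return An object of class `metrics_report`: list with `mrd_percent`,
#'   `rmsd_arith`, `rmsd_log`, `e_arith`, `e_log` and `n_points`. Stored
#'   values are unscaled; presentation factors (1e5 for RMSD1, 100 for
#'   RMSD2) belong to the reporting layer only.
#' @export
metrics_report <- function(bc) {
  v <- .bc_vectors(bc); .check_nonempty(v)
  structure(
    list(mrd_percent = mrd_percent(bc),
         rmsd_arith = rmsd_arith(bc),
         rmsd_log = rmsd_log(bc),
         e_arith = e_arith(bc),
         e_log = e_log(bc),
         n_points = length(v$x_exp)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> N =", x$n_points, "\n")
  cat(sprintf("  MRD%%  : %.4g\n", x$mrd_percent))
  cat(sprintf("  RMSD1 : %.6g   (1e5 * RMSD1 = %.4g)\n",
              x$rmsd_arith, 1e5 * x$rmsd_arith))
  cat(sprintf("  RMSD2 : %.6g   (100 * RMSD2 = %.4g)\n",
              x$rmsd_log, 100 * x$rmsd_log))
  cat(sprintf("  E1    : %.6g\n", x$e_arith))
  cat(sprintf("  E2    : %.6g\n", x$e_log))
  invisible(x)
}

.metric_names <- c("mrd_percent", "rmsd_arith", "rmsd_log", "e_arith",
                   "e_log")

#' Correlate error criteria across datasets
#'
#' Given one metrics report per dataset, computes the Pearson and Spearman
#' correlation of every criterion against a reference criterion (MRD% by
#' default). A criterion that is constant across datasets has undefined
#' correlation; it is flagged `degenerate` with NA correlations rather than
#' dropped.
#'
#' @param reports A list of [metrics_report()] objects (>= 3), or a
#'   data.frame with the metric columns.
#' @param reference Name of the reference metric column.
#' @return data.frame with columns `metric`, `pearson`, `spearman`,
#'   `degenerate`.
#' @export
correlate_metrics <- function(reports, reference = "mrd_percent") {
  if (is.data.frame(reports)) {
    tab <- reports
  } else {
    stopifnot(is.list(reports))
    tab <- do.call(rbind, lapply(reports, function(m) {
      as.data.frame(m[.metric_names])
    }))
  }
  if (nrow(tab) < 3L) stop("need at least 3 reports", call. = FALSE)
  if (!reference %in% names(tab)) {
    stop("unknown reference metric '", reference, "'", call. = FALSE)
  }
  ref <- tab[[reference]]
  others <- setdiff(intersect(.metric_names, names(tab)), reference)
  res <- lapply(others, function(m) {
    v <- tab[[m]]
    degen <- stats::sd(v) == 0 || stats::sd(ref) == 0
    data.frame(
      metric = m,
      pearson = if (degen) NA_real_ else stats::cor(v, ref),
      spearman = if (degen) NA_real_ else
        stats::cor(v, ref, method = "spearman"),
      degenerate = degen
    )
  })
  do.call(rbind, res)
}
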