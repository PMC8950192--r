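# Comparative study orchestration: fit every dataset under every requested
# unit code, collect the five error criteria, aggregate per code and per
# drug, diagnose composition skew across bases, and run single-datum
# perturbation experiments.

#' Analyse one dataset under one unit code
#'
#' Convert, fit, back-calculate and score, deterministically.
#'
#' @param dataset A [solubility_dataset()].
#' @param code A [unit_code()] or integer 1-9.
#' @param np Highest interaction power (see [build_regression()]).
#' @param prune,alpha Backward-elimination options (see [fit_ja()]).
#' @return List with elements `fit` ([fit_ja()] result), `metrics`
#'   ([metrics_report()]), `back_calc` and `conv`.
#' @export
run_code_analysis <- function(dataset, code, np = 2L, prune = FALSE,
                              alpha = 0.05) {
  code <- unit_code(code)
  conv <- convert_dataset(dataset, code)
  fit <- fit_ja(conv, np = np, prune = prune, alpha = alpha)
  bc <- back_calculate(fit, conv)
  list(fit = fit, metrics = metrics_report(bc), back_calc = bc, conv = conv)
}

#' Run the full comparative study
#'
#' Fits every (dataset, code) pair, records failures without aborting, and
#' aggregates: overall mean and SD of MRD% per code across datasets,
#' per-drug mean E1 and MRD% per code, and the composition-skew table
#' (mean solvent-1 fraction per dataset in each of the three bases).
#'
#' @param datasets Non-empty list of [solubility_dataset()] objects.
#' @param codes Integer subset of 1-9.
#' @inheritParams run_code_analysis
#' @param correlations If TRUE (default) and enough datasets, include the
#'   [correlate_metrics()] table against MRD%, computed per code.
#' @param verbose If TRUE, log each fit.
#' @return An object of class `study_summary` with data.frames `results`,
#'   `overall`, `per_drug`, `skew`, `correlations` and a list `failures`.
#' @export
run_full_study <- function(datasets, codes = 1:9, np = 2L, prune = FALSE,
                           alpha = 0.05, correlations = TRUE,
                           verbose = FALSE) {
  if (length(datasets) == 0L) stop("no datasets supplied", call. = FALSE)
  if (inherits(datasets, "solubility_dataset")) datasets <- list(datasets)
  codes <- vapply(codes, function(x) unit_code(x)$code, integer(1))

  rows <- list()
  failures <- list()
  for (ds in datasets) {
    for (cd in codes) {
      res <- tryCatch(
        run_code_analysis(ds, cd, np = np, prune = prune, alpha = alpha),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(dataset = ds$label, code = cd, reason = conditionMessage(res))
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds$label, drug = ds$drug$name, code = cd, ok = FALSE,
          n_points = NA_integer_, mrd_percent = NA_real_,
          rmsd_arith = NA_real_, rmsd_log = NA_real_, e_arith = NA_real_,
          e_log = NA_real_, J0 = NA_real_, J1 = NA_real_, J2 = NA_real_,
          J3 = NA_real_, J4 = NA_real_,
          retained = NA_character_
        )
        next
      }
      if (verbose) {
        message(sprintf("fit %s code %d: retained %s", ds$label, cd,
                        paste(names(which(res$fit$retained)),
                              collapse = ",")))
      }
      J <- rep(NA_real_, 5L)
      J[seq_along(res$fit$coefficients)] <- res$fit$coefficients
      m <- res$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds$label, drug = ds$drug$name, code = cd, ok = TRUE,
        n_points = m$n_points, mrd_percent = m$mrd_percent,
        rmsd_arith = m$rmsd_arith, rmsd_log = m$rmsd_log,
        e_arith = m$e_arith, e_log = m$e_log,
        J0 = J[1], J1 = J[2], J2 = J[3], J3 = J[4], J4 = J[5],
        retained = paste(names(which(res$fit$retained)), collapse = ",")
      )
    }
  }
  results <- do.call(rbind, rows)

  ok <- results[results$ok, , drop = FALSE]
  overall <- do.call(rbind, lapply(codes, function(cd) {
    v <- ok$mrd_percent[ok$code == cd]
    data.frame(code = cd, n_datasets = length(v),
               mean_mrd_percent = mean(v), sd_mrd_percent = stats::sd(v))
  }))

  per_drug <- do.call(rbind, lapply(split(ok, list(ok$drug, ok$code),
                                          drop = TRUE), function(g) {
    data.frame(drug = g$drug[1], code = g$code[1],
               mean_e_arith = mean(g$e_arith),
               mean_mrd_percent = mean(g$mrd_percent))
  }))
  rownames(per_drug) <- NULL
  per_drug <- per_drug[order(per_drug$drug, per_drug$code), , drop = FALSE]

  skew <- do.call(rbind, lapply(datasets, function(ds) {
    s <- composition_skew(ds)
    data.frame(dataset = ds$label, mean_w1_mole = s[["mole"]],
               mean_w1_mass = s[["mass"]], mean_w1_volume = s[["volume"]])
  }))

  correl <- NULL
  if (correlations && sum(results$ok) >= 3L) {
    correl <- do.call(rbind, lapply(codes, function(cd) {
      sub <- ok[ok$code == cd, , drop = FALSE]
      if (nrow(sub) < 3L) return(NULL)
      out <- correlate_metrics(sub, reference = "mrd_percent")
      out$code <- cd
      out
    }))
  }

  structure(
    list(results = results, overall = overall, per_drug = per_drug,
         skew = skew, correlations = correl, failures = failures,
         options = list(codes = codes, np = np, prune = prune,
                        alpha = alpha)),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat("<study_summary>", length(unique(x$results$dataset)), "dataset(s) x",
      length(x$options$codes), "code(s);", length(x$failures),
      "failure(s)\n")
  cat("Overall MRD% per code:\n")
  print(x$overall, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Mean solvent-1 fraction in each composition basis
#'
#' Converts the dataset's compositions to each of the three bases and
#' averages over records. A grid uniform in one basis is skewed in another
#' whenever the solvent molar masses (or densities) differ — the mechanism
#' by which the choice of basis alters the model's fit quality.
#'
#' @param dataset A [solubility_dataset()].
#' @return Named numeric vector with elements `mole`, `mass`, `volume`.
#' @export
composition_skew <- function(dataset) {
  validate_dataset(dataset)
  r <- dataset$records
  M1 <- dataset$solvent1$molar_mass
  M2 <- dataset$solvent2$molar_mass
  rho1 <- dataset$solvent1$pure_density
  rho2 <- dataset$solvent2$pure_density
  vapply(SOLVENT_BASES, function(b) {
    mean(.convert_basis(r$w1, dataset$solvent_basis, b, M1, M2, rho1, rho2))
  }, numeric(1))
}

#' Single-datum perturbation experiment
#'
#' Multiplies one record's solubility by `factor` (or sets it to
#' `new_value`), refits the model under the given code, and reports all
#' five error criteria before and after. Perturbing a mono-solvent anchor
#' is permitted but flagged with a warning, since it shifts the model's
#' known inputs, not just one residual.
#'
#' @param dataset A [solubility_dataset()].
#' @param index Record index to perturb.
#' @param factor Positive multiplier (exclusive with `new_value`).
#' @param new_value Replacement solubility (exclusive with `factor`).
#' @param code Unit code for the analysis.
#' @inheritParams run_code_analysis
#' @return An object of class `perturbation_result` with the dataset label,
#'   perturbed index, original/perturbed values, `metrics_before`,
#'   `metrics_after` and `anchor` flag.
#' @export
perturb_and_compare <- function(dataset, index, factor = NULL,
                                new_value = NULL, code = 4L, np = 2L,
                                prune = FALSE, alpha = 0.05) {
  validate_dataset(dataset)
  index <- as.integer(index)
  if (index < 1L || index > nrow(dataset$records)) {
    stop("record index out of range", call. = FALSE)
  }
  if (is.null(factor) == is.null(new_value)) {
    stop("supply exactly one of 'factor' or 'new_value'", call. = FALSE)
  }
  original <- dataset$records$solubility[index]
  if (is.null(factor)) {
    if (!is.finite(new_value) || new_value <= 0) {
      stop("perturbed value must be positive", call. = FALSE)
    }
    factor <- new_value / original
  }
  w1 <- dataset$records$w1[index]
  anchor <- w1 <= .endpoint_tol || w1 >= 1 - .endpoint_tol
  if (anchor) {
    warning("perturbing a mono-solvent anchor record alters the model's ",
            "known inputs x1,T/x2,T", call. = FALSE)
  }
  perturbed <- inject_outlier(dataset, index, factor)
  before <- run_code_analysis(dataset, code, np = np, prune = prune,
                              alpha = alpha)
  after <- run_code_analysis(perturbed, code, np = np, prune = prune,
                             alpha = alpha)
  structure(
    list(dataset_label = dataset$label, index = index,
         original_value = original,
         perturbed_value = original * factor,
         factor = factor, code = unit_code(code)$code, anchor = anchor,
         metrics_before = before$metrics, metrics_after = after$metrics),
    class = "perturbation_result"
  )
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("<perturbation_result> '", x$dataset_label, "', record ", x$index,
      ": ", format(x$original_value), " -> ", format(x$perturbed_value),
      " (x", format(x$factor), "), code ", x$code,
      if (x$anchor) " [anchor]" else "", "\n", sep = "")
  tab <- data.frame(
    before = unlist(x$metrics_before[.metric_names]),
    after = unlist(x$metrics_after[.metric_names])
  )
  print(tab, digits = 5)
  invisible(x)
}

#' Write a study summary to CSV files
#'
#' Emits `summary.csv` (per dataset x code), `overall.csv` (per code),
#' `per_drug.csv`, `skew.csv` and, when computed, `correlations.csv`.
#'
#' @param summary A [run_full_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "study_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(summary$results, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$overall, file.path(dir, "overall.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$per_drug, file.path(dir, "per_drug.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$skew, file.path(dir, "skew.csv"),
                   row.names = FALSE)
  if (!is.null(summary$correlations)) {
    utils::write.csv(summary$correlations,
                     file.path(dir, "correlations.csv"), row.names = FALSE)
  }
  invisible(dir)
}
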