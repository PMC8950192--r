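# The Jouyban-Acree cosolvency model:
#
#   ln x_m,T = w1 ln x1,T + w2 ln x2,T + (w1 w2 / T) * sum_{i=0}^{np} Ji (w1 - w2)^i
#
# with w2 = 1 - w1 (solute-free). The J coefficients (units of kelvin) are
# estimated by ordinary least squares of the excess-log response
# y = ln x_m,T - w1 ln x1,T - w2 ln x2,T on regressors w1 w2 (w1 - w2)^i / T,
# no intercept. With all J = 0 the model reduces to the log-linear ideal
# mixing rule (Yalkowsky).

#' Build the excess-log regression system
#'
#' Pure-solvent records (`w1` at 0 or 1) contribute identically zero
#' regressors and response and are excluded from the rows; they remain part
#' of back-calculation and error metrics.
#'
#' @param conv A [convert_dataset()] result.
#' @param np Highest power of `(w1 - w2)` in the interaction sum, 0-4;
#'   `np = 2` gives the usual three coefficients J0, J1, J2.
#' @return A list with response vector `y`, design matrix `X` (columns
#'   `J0..Jnp`), and `rows` (indices of the source records used).
#' @export
build_regression <- function(conv, np = 2L) {
  stopifnot(inherits(conv, "converted_dataset"))
  np <- as.integer(np)
  if (length(np) != 1L || is.na(np) || np < 0L || np > 4L) {
    stop("np must be a single integer in 0..4", call. = FALSE)
  }
  d <- conv$data
  mixed <- which(d$w1 > .endpoint_tol & d$w1 < 1 - .endpoint_tol)
  if (length(mixed) < np + 1L) {
    stop("underdetermined system: ", length(mixed),
         " mixed-composition rows for ", np + 1L, " coefficients",
         call. = FALSE)
  }
  w1 <- d$w1[mixed]
  w2 <- 1 - w1
  y <- log(d$xm[mixed]) - w1 * log(d$x1T[mixed]) - w2 * log(d$x2T[mixed])
  X <- vapply(0:np, function(i) w1 * w2 * (w1 - w2)^i / d$T[mixed],
              numeric(length(mixed)))
  X <- matrix(X, nrow = length(mixed),
              dimnames = list(NULL, paste0("J", 0:np)))
  list(y = y, X = X, rows = mixed)
}

# OLS with no intercept on a fixed design; returns coefficients, standard
# errors and two-sided t-test p-values (df = n - p). With zero residual
# degrees of freedom the inference columns are NaN.
.ols <- function(X, y) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dependent <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient design: column(s) ",
         paste(dependent, collapse = ", "), " are collinear", call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) sum(res^2) / df else NaN
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = max(df, 1L))
  list(beta = beta, se = se, p = pval, df = df, rss = sum(res^2))
}

#' Fit the Jouyban-Acree model
#'
#' Ordinary least squares without intercept on the [build_regression()]
#' system. With `prune = TRUE`, backward elimination repeatedly removes the
#' single retained term with the largest two-sided p-value above `alpha`
#' (ties broken by dropping the higher-order term) and refits, until all
#' retained terms are significant or one term remains. Pruned coefficients
#' are reported as exactly 0.
#'
#' @inheritParams build_regression
#' @param prune Enable backward elimination of non-significant terms.
#' @param alpha Significance level for retention (default 0.05).
#' @return An object of class `ja_fit` with full-length `coefficients`
#'   (pruned entries 0), `standard_errors`, `p_values` (NA for pruned
#'   terms), logical `retained`, `np`, `n_regression_points`, `code`,
#'   `dataset_label` and the residual sum of squares `rss`.
#' @export
fit_ja <- function(conv, np = 2L, prune = FALSE, alpha = 0.05) {
  sys <- build_regression(conv, np)
  k <- ncol(sys$X)
  retained <- rep(TRUE, k)
  repeat {
    ols <- .ols(sys$X[, retained, drop = FALSE], sys$y)
    if (!prune || sum(retained) == 1L) break
    p <- ols$p
    if (all(is.finite(p)) && any(p > alpha)) {
      # among the worst p-values, drop the highest-order term
      worst <- which(p == max(p))
      drop_local <- worst[length(worst)]
      retained[which(retained)[drop_local]] <- FALSE
    } else break
  }
  coefficients <- numeric(k)
  se <- rep(NA_real_, k)
  pv <- rep(NA_real_, k)
  coefficients[retained] <- ols$beta
  se[retained] <- ols$se
  pv[retained] <- ols$p
  names(coefficients) <- names(se) <- names(pv) <- colnames(sys$X)
  structure(
    list(coefficients = coefficients, standard_errors = se, p_values = pv,
         retained = stats::setNames(retained, colnames(sys$X)),
         np = np, n_regression_points = length(sys$y),
         code = conv$code, dataset_label = conv$source_label,
         rss = ols$rss, df_residual = ols$df,
         pruning = list(enabled = prune, alpha = alpha)),
    class = "ja_fit"
  )
}

#' @export
print.ja_fit <- function(x, ...) {
  cat("<ja_fit> '", x$dataset_label, "', code ", x$code$code,
      ", np = ", x$np, ", n = ", x$n_regression_points, " rows\n", sep = "")
  tab <- data.frame(J = x$coefficients, se = x$standard_errors,
                    p = x$p_values, retained = x$retained)
  print(tab, digits = 6)
  invisible(x)
}

#' Predict the log-solubility of a mixture
#'
#' Evaluates the model at composition `w1` and temperature `T` given the
#' log mono-solvent solubilities. At `w1 = 1` this returns `ln_x1` exactly;
#' at `w1 = 0`, `ln_x2`.
#'
#' @param fit A `ja_fit` (or any numeric coefficient vector via
#'   [predict_ln_solubility_coef()]).
#' @param w1 Solvent-1 fraction(s) in \[0, 1\] (the fit's basis).
#' @param T Absolute temperature(s) in K.
#' @param ln_x1,ln_x2 Natural-log mono-solvent solubilities at `T`, in the
#'   fit's solute unit.
#' @return Predicted ln solubility, same length as `w1`.
#' @export
predict_ln_solubility <- function(fit, w1, T, ln_x1, ln_x2) {
  stopifnot(inherits(fit, "ja_fit"))
  predict_ln_solubility_coef(fit$coefficients, w1, T, ln_x1, ln_x2)
}

#' Evaluate the model forward from raw coefficients
#'
#' @param J Numeric vector of coefficients (J0, J1, ...), in kelvin.
#' @inheritParams predict_ln_solubility
#' @return Predicted ln solubility.
#' @export
predict_ln_solubility_coef <- function(J, w1, T, ln_x1, ln_x2) {
  stopifnot(all(w1 >= 0 & w1 <= 1), all(T > 0))
  J <- as.numeric(J)
  w2 <- 1 - w1
  interaction <- numeric(length(w1))
  for (i in seq_along(J)) {
    interaction <- interaction + J[i] * (w1 - w2)^(i - 1L)
  }
  w1 * ln_x1 + w2 * ln_x2 + (w1 * w2 / T) * interaction
}

#' Ideal log-linear mixing prediction (Yalkowsky limit)
#'
#' `ln x_m = w1 ln x1 + w2 ln x2`, the special case of the model with all
#' J coefficients zero.
#'
#' @inheritParams predict_ln_solubility
#' @return Predicted ln solubility.
#' @export
yalkowsky_predict <- function(w1, ln_x1, ln_x2) {
  stopifnot(all(w1 >= 0 & w1 <= 1))
  w1 * ln_x1 + (1 - w1) * ln_x2
}

#' Back-calculate solubilities from a fit
#'
#' Evaluates the fitted model at every record of a converted dataset,
#' including the pure-solvent anchors (which reproduce themselves exactly),
#' using the experimental anchor solubilities at each record's temperature.
#'
#' @param fit A `ja_fit`.
#' @param conv The [convert_dataset()] result the fit was produced from (or
#'   a compatible one).
#' @return An object of class `back_calculation`: a data.frame with columns
#'   `x_exp` and `x_cal`, one row per record.
#' @export
back_calculate <- function(fit, conv) {
  stopifnot(inherits(fit, "ja_fit"), inherits(conv, "converted_dataset"))
  d <- conv$data
  if (any(is.na(d$x1T)) || any(is.na(d$x2T))) {
    stop("missing mono-solvent anchor for some records", call. = FALSE)
  }
  ln_cal <- predict_ln_solubility(fit, d$w1, d$T, log(d$x1T), log(d$x2T))
  structure(data.frame(x_exp = d$xm, x_cal = exp(ln_cal)),
            class = c("back_calculation", "data.frame"))
}

#' Serialise a fit to JSON
#'
#' @param fit A `ja_fit`.
#' @param path Optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "ja_fit"))
  obj <- list(
    dataset_label = fit$dataset_label,
    code = fit$code$code,
    np = fit$np,
    n_regression_points = fit$n_regression_points,
    coefficients = as.list(fit$coefficients),
    standard_errors = as.list(fit$standard_errors),
    p_values = as.list(fit$p_values),
    retained = as.list(fit$retained)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
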