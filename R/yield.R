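#' Shapiro-Wilk normality screen
#'
#' Normality check applied to yield and canopy-proxy variables before
#' correlation and regression analysis; normality is rejected when the
#' p-value falls below 0.05.
#'
#' @param values Numeric vector, n >= 3, not all identical.
#' @return The Shapiro-Wilk p-value.
#' @export
normality_test <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (max(values) - min(values) == 0) {
    stop("values are constant; normality is undefined", call. = FALSE)
  }
  stats::shapiro.test(values)$p.value
}

#' Abundance-weighted yield predictors
#'
#' Builds the four predictor families compared in the yield analysis from a
#' plot-level vegetation index: the index alone, or the index multiplied by
#' leaf abundance (`L`), panicle abundance (`P`), or their difference
#' (`LP`).
#'
#' @param vi Numeric vector of plot-level index values.
#' @param table Plot table carrying `Abd_L` and `Abd_P` columns (e.g. from
#'   [aggregate_abundance()]).
#' @param mode One of "plain", "L", "P", "LP".
#' @return Numeric predictor vector, same length as `vi`.
#' @examples
#' tab <- data.frame(Abd_L = 0.90, Abd_P = 0.06)
#' combined_index(0.5, tab, "LP")  # 0.5 * (0.90 - 0.06)
#' @export
combined_index <- function(vi, table, mode = c("plain", "L", "P", "LP")) {
  mode <- match.arg(mode)
  if (mode != "plain") {
    if (!all(c("Abd_L", "Abd_P") %in% names(table))) {
      stop("plot table lacks the Abd_L / Abd_P columns", call. = FALSE)
    }
    if (nrow(table) != length(vi)) {
      stop("vi and table lengths differ", call. = FALSE)
    }
  }
  switch(mode,
         plain = vi,
         L = vi * table$Abd_L,
         P = vi * table$Abd_P,
         LP = vi * (table$Abd_L - table$Abd_P))
}

#' Pearson correlation of predictors with yield
#'
#' Pearson r for each predictor against yield, with two-sided t-test
#' significance flags at the 0.05 (`*`) and 0.01 (`**`) levels, matching
#' the convention of correlation tables in field trials. No multiplicity
#' correction is applied across predictors.
#'
#' @param yield Numeric yield vector.
#' @param predictors Named list (or data frame) of numeric predictor
#'   vectors of the same length.
#' @return Data frame with `predictor`, `r`, `p_value`, `stars`.
#' @export
correlate <- function(yield, predictors) {
  yield <- as.numeric(yield)
  if (length(yield) < 3) stop("need at least 3 plots", call. = FALSE)
  if (stats::var(yield) == 0) stop("yield has zero variance", call. = FALSE)
  out <- lapply(names(predictors), function(nm) {
    x <- as.numeric(predictors[[nm]])
    if (length(x) != length(yield)) {
      stop("predictor '", nm, "' has the wrong length", call. = FALSE)
    }
    if (stats::var(x) == 0) {
      stop("predictor '", nm, "' has zero variance", call. = FALSE)
    }
    ct <- stats::cor.test(x, yield)
    data.frame(predictor = nm, r = unname(ct$estimate),
               p_value = ct$p.value,
               stars = if (ct$p.value < 0.01) "**"
                       else if (ct$p.value < 0.05) "*" else "")
  })
  do.call(rbind, out)
}

#' Simple linear yield regression
#'
#' Ordinary least-squares fit `yield = slope * x + intercept` with the
#' summaries used throughout the analysis: Pearson r, adjusted R-squared
#' `1 - (1 - R2) * (n - 1) / (n - 2)`, RMSE computed over all n residuals
#' (`sqrt(mean(residual^2))`), and the F-test p-value.
#'
#' @param predictor Numeric vector.
#' @param yield Numeric vector, same length, n >= 3.
#' @return A `regression_result` list: `slope`, `intercept`, `pearson_r`,
#'   `r_squared`, `adjusted_r2`, `rmse`, `p_value`, `n`.
#' @examples
#' fit_linear(1:10, 2 * (1:10) + 1)  # slope 2, intercept 1, RMSE 0
#' @export
fit_linear <- function(predictor, yield) {
  x <- as.numeric(predictor)
  y <- as.numeric(yield)
  n <- length(x)
  if (n != length(y)) stop("lengths differ", call. = FALSE)
  if (n < 3) stop("need at least 3 plots", call. = FALSE)
  if (max(x) - min(x) == 0) {
    stop("constant predictor: singular fit", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; those are legitimate here (noiseless
  # synthetic data) and the R2/F statistics remain well-defined
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  res <- structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = sign(stats::coef(fit)[2]) * sqrt(r2),
    r_squared = r2,
    adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
    rmse = sqrt(mean(stats::residuals(fit)^2)),
    p_value = if (r2 == 1) 0 else
      unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                       lower.tail = FALSE)),
    n = n), class = "regression_result")
  res$pearson_r <- unname(res$pearson_r)
  res
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> n=%d  yield = %.4g x + %.4g\n  r=%.3f  adjR2=%.3f  RMSE=%.4g  p=%.3g\n",
    x$n, x$slope, x$intercept, x$pearson_r, x$adjusted_r2, x$rmse, x$p_value))
  invisible(x)
}

#' Leave-one-out cross-validated yield model
#'
#' Fits the simple linear yield model K times (K = number of plots),
#' leaving out one plot per fold: fold i trains on the other K - 1 plots,
#' giving coefficients `Coef_i` and the training coefficient of
#' determination `R2_i`, and predicts the held-out plot with error `E_i`
#' (predicted minus observed). The reported model is the fold average:
#' coefficients are `mean(Coef_i)`, the cross-validated R-squared is
#' `mean(R2_i)` (a training-set quantity, hence optimistic), and RMSE is
#' `sqrt(mean(E_i^2))` over the held-out errors.
#'
#' @param predictor Numeric vector.
#' @param yield Numeric vector, same length, n >= 4.
#' @return A `cv_result` list: `fold_coefficients` (K x 2 matrix, slope and
#'   intercept), `fold_r2`, `fold_errors`, `slope`, `intercept`, `r_squared`,
#'   `rmse`, `K`.
#' @export
loocv_fit <- function(predictor, yield) {
  x <- as.numeric(predictor)
  y <- as.numeric(yield)
  K <- length(x)
  if (K != length(y)) stop("lengths differ", call. = FALSE)
  if (K < 4) stop("need at least 4 plots for leave-one-out", call. = FALSE)
  coefs <- matrix(NA_real_, K, 2, dimnames = list(NULL, c("slope", "intercept")))
  r2 <- err <- numeric(K)
  for (i in seq_len(K)) {
    fit <- fit_linear(x[-i], y[-i])
    coefs[i, ] <- c(fit$slope, fit$intercept)
    r2[i] <- fit$r_squared
    err[i] <- (fit$slope * x[i] + fit$intercept) - y[i]
  }
  structure(list(fold_coefficients = coefs, fold_r2 = r2, fold_errors = err,
                 slope = mean(coefs[, 1]), intercept = mean(coefs[, 2]),
                 r_squared = mean(r2), rmse = sqrt(mean(err^2)), K = K),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> K=%d folds  yield = %.4g x + %.4g\n  R2=%.3f  RMSE=%.4g\n",
    x$K, x$slope, x$intercept, x$r_squared, x$rmse))
  invisible(x)
}

#' Rank abundance-weighted index models
#'
#' Fits `yield ~ predictor` for every combination of vegetation index and
#' weighting mode and returns the grid sorted by adjusted R-squared, along
#' with the sign of the Pearson correlation, mirroring how competing
#' index families are compared.
#'
#' @param table Plot table containing a `yield` column, one column per
#'   index in `vi_names`, and `Abd_L` / `Abd_P`.
#' @param vi_names Character vector of index column names to use.
#' @param modes Weighting modes, a subset of `c("plain", "L", "P", "LP")`.
#' @param exclude_plots Optional plot_ids to drop before fitting (e.g.
#'   records known to be erroneous); default none.
#' @return Data frame with one row per (index, mode): `vi`, `mode`,
#'   `predictor`, `r`, `adjusted_r2`, `rmse`, `p_value`, sorted by
#'   decreasing adjusted R-squared.
#' @export
rank_models <- function(table, vi_names, modes = c("plain", "L", "P", "LP"),
                        exclude_plots = NULL) {
  if (!is.null(exclude_plots)) {
    table <- table[!table$plot_id %in% exclude_plots, , drop = FALSE]
  }
  missing <- setdiff(c("yield", vi_names), names(table))
  if (length(missing)) {
    stop("plot table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grid <- expand.grid(vi = vi_names, mode = modes, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    vi <- grid$vi[i]
    mode <- grid$mode[i]
    pred <- combined_index(table[[vi]], table, mode)
    fit <- fit_linear(pred, table$yield)
    data.frame(vi = vi, mode = mode,
               predictor = if (mode == "plain") vi else
                 paste0(vi, " x Abd_", sub("LP", "L-P", mode)),
               r = fit$pearson_r, adjusted_r2 = fit$adjusted_r2,
               rmse = fit$rmse, p_value = fit$p_value)
  })
  out <- do.call(rbind, rows)
  out[order(-out$adjusted_r2), ]
}
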