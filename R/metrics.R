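check_pair <- function(observed, predicted, min_n = 1L) {
  if (!is.numeric(observed) || !is.numeric(predicted)) {
    stop("observed and predicted must be numeric", call. = FALSE)
  }
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have the same length", call. = FALSE)
  }
  if (length(observed) < min_n) {
    stop(sprintf("need at least %d paired values", min_n), call. = FALSE)
  }
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("observed and predicted must be finite", call. = FALSE)
  }
  invisible(NULL)
}

#' Root mean square error
#'
#' @param observed,predicted paired numeric vectors.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  check_pair(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' Normalized RMSE, in percent
#'
#' RMSE divided by either the observed range (`max - min`, the default) or
#' the observed mean, times 100. Which normalizer produced a printed number
#' matters when comparing across studies, so the mode is explicit.
#'
#' @param observed,predicted paired numeric vectors.
#' @param mode `"range"` or `"mean"`.
#' @return nRMSE in percent.
#' @export
nrmse <- function(observed, predicted, mode = c("range", "mean")) {
  mode <- match.arg(mode)
  check_pair(observed, predicted)
  denom <- if (mode == "range") {
    diff(range(observed))
  } else {
    mean(observed)
  }
  if (abs(denom) < .Machine$double.eps) {
    stop("undefined normalization: zero ", mode, " of observed values",
         call. = FALSE)
  }
  100 * rmse(observed, predicted) / denom
}

#' Mean absolute error
#'
#' @param observed,predicted paired numeric vectors.
#' @return `mean(abs(observed - predicted))`.
#' @export
mae <- function(observed, predicted) {
  check_pair(observed, predicted)
  mean(abs(observed - predicted))
}

#' Pearson correlation between observed and predicted
#'
#' @param observed,predicted paired numeric vectors, both non-constant.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_cc <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 2L)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(observed, predicted)
}

#' Coefficient of determination for observed-vs-predicted scatter
#'
#' The default is the squared Pearson correlation, the quantity a scatter
#' plot's fitted-line R-squared reports and the definition under which
#' `r2 == pearson_cc^2` holds identically. The sums-of-squares alternative
#' `1 - SSE/SST` (which penalizes bias, and can be negative) is available
#' via `method = "ss"`.
#'
#' @param observed,predicted paired numeric vectors.
#' @param method `"pearson"` (default) or `"ss"`.
#' @return R-squared as a proportion.
#' @export
r2 <- function(observed, predicted, method = c("pearson", "ss")) {
  method <- match.arg(method)
  check_pair(observed, predicted, min_n = 2L)
  if (method == "pearson") {
    pearson_cc(observed, predicted)^2
  } else {
    sst <- sum((observed - mean(observed))^2)
    if (sst == 0) stop("undefined R2: constant observed vector", call. = FALSE)
    1 - sum((observed - predicted)^2) / sst
  }
}

#' Relative absolute error
#'
#' Total absolute error relative to that of the constant mean predictor:
#' `sum(|O - P|) / sum(|O - mean(O)|)`.
#'
#' @param observed,predicted paired numeric vectors.
#' @return RAE as a proportion (1 for the mean predictor).
#' @export
rae <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 2L)
  denom <- sum(abs(observed - mean(observed)))
  if (denom == 0) stop("undefined RAE: constant observed vector", call. = FALSE)
  sum(abs(observed - predicted)) / denom
}

#' Root relative squared error
#'
#' `sqrt(sum((O - P)^2) / sum((O - mean(O))^2))`.
#'
#' @param observed,predicted paired numeric vectors.
#' @return RRSE as a proportion (1 for the mean predictor).
#' @export
rrse <- function(observed, predicted) {
  check_pair(observed, predicted, min_n = 2L)
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) stop("undefined RRSE: constant observed vector", call. = FALSE)
  sqrt(sum((observed - predicted)^2) / denom)
}

#' Fraction of predictions inside the +/-25 percent error band
#'
#' A prediction is inside the band when `|P - O| <= band * O` for a positive
#' observation. The band collapses to a point at `O == 0`, so zero
#' observations instead use an absolute tolerance `zero_tol` on the
#' prediction itself.
#'
#' @param observed,predicted paired numeric vectors; observed >= 0.
#' @param band half-width of the relative band (default 0.25).
#' @param zero_tol absolute tolerance for pairs with observed == 0, in score
#'   units (default 0.01).
#' @return fraction of pairs inside the band, in \[0, 1\].
#' @export
coverage_error_line <- function(observed, predicted, band = 0.25,
                                zero_tol = 0.01) {
  check_pair(observed, predicted)
  ok <- ifelse(observed == 0,
               abs(predicted) <= zero_tol,
               abs(predicted - observed) <= band * observed)
  mean(ok)
}

#' Variance inflation factors of a design matrix
#'
#' For each column j, `1 / (1 - R2_j)` where `R2_j` is the R-squared from
#' regressing column j on all other columns (with intercept).
#'
#' @param design numeric matrix or data.frame of predictor columns.
#' @return named numeric vector of VIFs, one per column.
#' @export
vif <- function(design) {
  x <- as.matrix(design)
  if (!is.numeric(x)) stop("design must be numeric", call. = FALSE)
  if (ncol(x) < 2L) stop("VIF needs at least two columns", call. = FALSE)
  if (nrow(x) < ncol(x) + 1L) {
    stop("VIF needs more rows than columns", call. = FALSE)
  }
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    sst <- sum((x[, j] - mean(x[, j]))^2)
    r2j <- 1 - sum(fit$residuals^2) / sst
    if (r2j > 1 - 1e-12) {
      stop("singular design: column ", j,
           " is perfectly collinear with the others", call. = FALSE)
    }
    1 / (1 - r2j)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' Pairwise Pearson correlation matrix
#'
#' @param table data.frame or matrix of numeric columns (>= 3 rows, all
#'   columns non-constant).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("all columns must be numeric", call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 rows", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    stop("undefined correlation: constant column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::cor(x)
}

#' All evaluation metrics for one prediction set, as a flat record
#'
#' @param observed,predicted paired numeric vectors.
#' @param band,zero_tol passed to [coverage_error_line()].
#' @return one-row data.frame with columns `r2`, `rmse`, `nrmse_range`,
#'   `nrmse_mean`, `mae`, `rae`, `rrse`, `cc`, `coverage25`, `n`.
#' @export
evaluate_predictions <- function(observed, predicted, band = 0.25,
                                 zero_tol = 0.01) {
  check_pair(observed, predicted, min_n = 2L)
  data.frame(
    r2 = r2(observed, predicted),
    rmse = rmse(observed, predicted),
    nrmse_range = nrmse(observed, predicted, "range"),
    nrmse_mean = nrmse(observed, predicted, "mean"),
    mae = mae(observed, predicted),
    rae = rae(observed, predicted),
    rrse = rrse(observed, predicted),
    cc = pearson_cc(observed, predicted),
    coverage25 = coverage_error_line(observed, predicted, band, zero_tol),
    n = length(observed)
  )
}
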