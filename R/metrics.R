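#' Root mean square error
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (!length(y)) stopf("rmse of empty input")
  if (length(y) != length(yhat)) stopf("rmse: length mismatch")
  sqrt(mean((y - yhat)^2))
}

#' Regression slope used by the fit-quality statistic
#'
#' Two modes are provided because the printed definition of the slope is
#' internally inconsistent with the conventional through-origin slope used
#' in QSAR validation:
#' * `"literal"` (default): `k = sum(y * yhat) / sum(mean(y)^2)`, i.e. the
#'   denominator is `N * mean(y)^2`.
#' * `"standard"`: the regression-through-origin slope
#'   `k = sum(y * yhat) / sum(yhat^2)`.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @param mode `"literal"` or `"standard"`.
#' @return the slope, or `NA` with attribute `undefined = TRUE` when the
#'   denominator is zero.
#' @export
slopeK <- function(y, yhat, mode = c("literal", "standard")) {
  mode <- match.arg(mode)
  stopifnot(length(y) == length(yhat))
  den <- if (mode == "literal") length(y) * mean(y)^2 else sum(yhat^2)
  if (den == 0) return(structure(NA_real_, undefined = TRUE))
  sum(y * yhat) / den
}

#' Fit statistic in the publication form
#'
#' `R2 = 1 - sum((y - y_r0)^2) / sum((y - yhat)^2)` with the baseline
#' `y_r0 = k * mean(y)` built from [slopeK()]. The denominator is the
#' residual sum of squares (not the total variance of the conventional
#' coefficient of determination), so the statistic is undefined at perfect
#' prediction; in that case `NA` is returned with attribute
#' `undefined = TRUE` rather than raising an error.
#'
#' @inheritParams slopeK
#' @param mode slope mode passed to [slopeK()] (`"literal"` default).
#' @return the statistic, or flagged `NA` when its denominator is 0.
#' @seealso [r2Conventional()] for the textbook definition.
#' @export
r2Paper <- function(y, yhat, mode = c("literal", "standard")) {
  mode <- match.arg(mode)
  stopifnot(length(y) == length(yhat))
  den <- sum((y - yhat)^2)
  if (den == 0) return(structure(NA_real_, undefined = TRUE))
  k <- slopeK(y, yhat, mode = mode)
  if (isTRUE(attr(k, "undefined"))) return(structure(NA_real_, undefined = TRUE))
  yr0 <- if (mode == "literal") rep(k * mean(y), length(y)) else k * yhat
  1 - sum((y - yr0)^2) / den
}

#' Conventional coefficient of determination
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`: the proportion of
#' variance in the observed response explained by the predictions. Equals 1
#' iff predictions are exact; can be negative for models worse than the
#' mean.
#'
#' @inheritParams rmse
#' @return scalar `<= 1`.
#' @export
r2Conventional <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stopf("r2Conventional undefined for constant observations")
  1 - sum((y - yhat)^2) / tss
}

#' Full metrics report for one prediction set
#'
#' @inheritParams rmse
#' @return one-row data.frame with `n`, `rmse`, `r2_conventional`,
#'   `r2_paper`, `r2_paper_defined`, and `slope_k` (literal mode).
#' @export
evaluatePredictions <- function(y, yhat) {
  rp <- r2Paper(y, yhat)
  k <- slopeK(y, yhat)
  data.frame(n = length(y),
             rmse = rmse(y, yhat),
             r2_conventional = r2Conventional(y, yhat),
             r2_paper = as.numeric(rp),
             r2_paper_defined = !isTRUE(attr(rp, "undefined")),
             slope_k = as.numeric(k))
}
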