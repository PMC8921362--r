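#' Fit the linear RC-versus-SA:V surrogate model
#'
#' Ordinary least squares of recovery coefficient (percent) on SA:V
#' (cm^-1) with equal weights for all points, in closed form. The fit
#' retains the predictor moments needed for Student-t prediction
#' intervals.
#'
#' @param sav SA:V values, cm^-1 (or a 2-column data frame / matrix of
#'   (sav, rc) pairs).
#' @param rc Recovery coefficients, percent.
#' @return A [RegressionFit-class].
#' @examples
#' f <- fitRCvsSAV(c(1, 2, 3), 100 - 16 * c(1, 2, 3))
#' fitSlope(f)       # -16
#' @export
fitRCvsSAV <- function(sav, rc) {
  if (missing(rc)) {
    rc <- sav[[2]]; sav <- sav[[1]]
  }
  ok <- is.finite(sav) & is.finite(rc)
  x <- as.numeric(sav[ok]); y <- as.numeric(rc[ok])
  n <- length(x)
  if (n < 3) stop("at least 3 points are required")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 1e-12 * mx^2) stop("degenerate predictor: all SA:V values equal")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  sd <- if (n > 2) sqrt(sum(res^2) / (n - 2)) else 0
  new("RegressionFit", slope = slope, intercept = intercept,
      rSquared = min(max(r2, 0), 1), residualSd = sd, n = as.integer(n),
      meanX = mx, sxx = sxx)
}

#' Predicted recovery coefficient at a given SA:V
#'
#' @param fit A [RegressionFit-class].
#' @param sav SA:V value(s), cm^-1.
#' @return Predicted RC in percent.
#' @export
predictRC <- function(fit, sav) fit@intercept + fit@slope * sav

#' Prediction interval for a new RC observation
#'
#' Standard OLS prediction interval with the Student-t quantile at
#' `n - 2` degrees of freedom:
#' `half = t * s * sqrt(1 + 1/n + (x - mean_x)^2 / sxx)`.
#'
#' @param fit A [RegressionFit-class] with at least 4 points.
#' @param sav SA:V value(s), cm^-1.
#' @param level Coverage level (default 0.95).
#' @return A data frame with columns `fit`, `low`, `high`, `half_width`.
#' @export
predictionInterval <- function(fit, sav, level = 0.95) {
  if (fit@n < 4) stop("prediction intervals need a fit with n >= 4")
  tq <- stats::qt(1 - (1 - level) / 2, df = fit@n - 2)
  mid <- predictRC(fit, sav)
  half <- tq * fit@residualSd *
    sqrt(1 + 1 / fit@n + (sav - fit@meanX)^2 / fit@sxx)
  data.frame(fit = mid, low = mid - half, high = mid + half,
             half_width = half)
}

#' Mean prediction-interval half width over observed predictors
#'
#' The average half width of the prediction band evaluated at the fitted
#' x values, the figure quoted alongside the published regression plots.
#'
#' @param fit A [RegressionFit-class].
#' @param sav The SA:V values the fit was computed from.
#' @param level Coverage level.
#' @return Mean half width in percent RC.
#' @export
meanPIHalfWidth <- function(fit, sav, level = 0.95) {
  mean(predictionInterval(fit, sav, level)$half_width)
}

#' Group summary as printed in the reference tables
#'
#' Mean and sample (n-1) standard deviation, with display values rounded
#' to one decimal (half-up) as in the published tables.
#'
#' @param values Numeric vector.
#' @return A data frame with `n`, `mean`, `sd`, `mean_display`,
#'   `sd_display` and a `single_value` flag (sd reported as 0 for n = 1).
#' @export
groupSummary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("empty group")
  m <- mean(values)
  s <- if (n >= 2) stats::sd(values) else 0
  data.frame(n = n, mean = m, sd = s,
             mean_display = roundHalfUp(m, 1), sd_display = roundHalfUp(s, 1),
             single_value = n == 1)
}
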