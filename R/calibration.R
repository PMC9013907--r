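## Calibration: unweighted OLS fit, homoscedasticity and linearity tests,
## back-calculation and the dual-range rule.

.checkCalibrationTable <- function(table) {
  need <- c("nominal_pg_per_mg", "response_ratio")
  if (!all(need %in% names(table)))
    stop("calibration table needs columns ", paste(need, collapse = ", "))
  if (any(table$response_ratio < 0))
    stop("response_ratio: must be >= 0")
  invisible(table)
}

#' Fit the calibration function
#'
#' Unweighted ordinary least squares of the response ratio on nominal
#' concentration (no weighting, as appropriate for homoscedastic
#' calibration data), retaining the diagnostics needed for prediction-band
#' detection limits.
#'
#' @param table `data.frame` with columns `nominal_pg_per_mg` and
#'   `response_ratio` (at least 3 distinct levels)
#' @return a [CalibrationFit]
#' @examples
#' fitCalibration(simulateCalibration(CalibrationSimSpec(noiseParam = 0)))
#' @export
fitCalibration <- function(table) {
  .checkCalibrationTable(table)
  x <- table$nominal_pg_per_mg
  y <- table$response_ratio
  if (length(unique(x)) < 3)
    stop("insufficient design: at least 3 distinct concentration levels required")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0)
    stop("degenerate design: zero concentration variance")
  fit <- lm(y ~ x)
  sse <- sum(resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  n <- length(x)
  new("CalibrationFit",
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      residualSd = sqrt(sse / (n - 2)), n = as.integer(n),
      meanX = mean(x), sxx = sxx,
      rSquared = if (sst > 0) 1 - sse / sst else NA_real_,
      range = range(x))
}

#' Fisher variance-ratio test for homoscedasticity
#'
#' Compares the replicate variances at the lowest and highest calibration
#' levels. Homoscedasticity is accepted (and unweighted regression
#' justified) when the variance ratio does not exceed the upper F critical
#' value.
#'
#' @param table calibration table with >= 2 replicates at each extreme level
#' @param alpha significance level (default 0.01)
#' @return list with `F`, `df` (numerator, denominator), `pass`, `alpha`
#' @export
fisherHomoscedasticityTest <- function(table, alpha = 0.01) {
  .checkCalibrationTable(table)
  x <- table$nominal_pg_per_mg
  lo <- table$response_ratio[x == min(x)]
  hi <- table$response_ratio[x == max(x)]
  if (length(lo) < 2 || length(hi) < 2)
    stop("need >= 2 replicates at the lowest and highest levels")
  v <- c(var(lo), var(hi))
  df <- c(length(lo), length(hi)) - 1L
  if (v[2] >= v[1]) { num <- 2; den <- 1 } else { num <- 1; den <- 2 }
  F <- if (v[den] == 0 && v[num] == 0) 1 else v[num] / v[den]
  list(F = F, df = c(df[num], df[den]),
       pass = F <= qf(1 - alpha, df[num], df[den]), alpha = alpha)
}

#' Lack-of-fit test for the linear calibration model
#'
#' Splits the residual sum of squares of the straight-line fit into pure
#' error (within-level replicate scatter) and lack of fit;
#' `F = (SS_lof / (k - 2)) / (SS_pe / (n - k))` with `k` levels and `n`
#' points. Linearity is accepted when F does not exceed the critical value.
#'
#' @param table calibration table with replication at >= 1 level and >= 3
#'   distinct levels
#' @param fit optional [CalibrationFit]; refitted from `table` when omitted
#' @param alpha significance level (default 0.05)
#' @return list with `F`, `df`, `pass`, `alpha`
#' @export
lackOfFitTest <- function(table, fit = NULL, alpha = 0.05) {
  .checkCalibrationTable(table)
  x <- table$nominal_pg_per_mg
  y <- table$response_ratio
  k <- length(unique(x))
  n <- length(x)
  if (k < 3) stop("insufficient design: at least 3 distinct levels required")
  if (n <= k)
    stop("pure error undefined: no replication at any level")
  if (is.null(fit)) fit <- fitCalibration(table)
  sse <- sum((y - (fit@intercept + fit@slope * x))^2)
  sspe <- sum(unlist(lapply(split(y, x), function(g) (g - mean(g))^2)))
  sslof <- max(sse - sspe, 0)
  eps <- .Machine$double.eps^0.5 * max(1, sum(y^2))
  F <- if (sspe <= eps) {
    if (sslof <= eps) 0 else Inf
  } else {
    (sslof / (k - 2)) / (sspe / (n - k))
  }
  df <- c(k - 2L, n - k)
  list(F = F, df = as.integer(df),
       pass = F <= qf(1 - alpha, df[1], df[2]), alpha = alpha)
}

#' Mandel test for linearity
#'
#' F test of the improvement of a quadratic over the linear calibration
#' model: `F = (SSE_lin - SSE_quad) / (SSE_quad / (n - 3))`. Linearity is
#' accepted when F does not exceed the critical value with (1, n - 3)
#' degrees of freedom.
#'
#' @param table calibration table with n >= 4 points
#' @param alpha significance level (default 0.05)
#' @return list with `F`, `df`, `pass`, `alpha`
#' @export
mandelTest <- function(table, alpha = 0.05) {
  .checkCalibrationTable(table)
  x <- table$nominal_pg_per_mg
  y <- table$response_ratio
  n <- length(x)
  if (n < 4) stop("Mandel test requires at least 4 points")
  sse1 <- sum(resid(lm(y ~ x))^2)
  sse2 <- sum(resid(lm(y ~ x + I(x^2)))^2)
  eps <- .Machine$double.eps^0.5 * max(1, sum(y^2))
  F <- if (sse2 <= eps) {
    if (sse1 - sse2 <= eps) 0 else Inf
  } else {
    max(sse1 - sse2, 0) / (sse2 / (n - 3))
  }
  df <- c(1L, as.integer(n - 3))
  list(F = F, df = df, pass = F <= qf(1 - alpha, df[1], df[2]),
       alpha = alpha)
}

#' Run all calibration diagnostics
#'
#' Convenience wrapper bundling the Fisher homoscedasticity test and both
#' linearity tests into a [LinearityVerdict].
#'
#' @param table calibration table
#' @param alpha significance level for the linearity tests (default 0.05)
#' @param fisherAlpha significance level for the Fisher test (default 0.01)
#' @param fit optional [CalibrationFit]
#' @return a [LinearityVerdict]
#' @export
linearityVerdict <- function(table, alpha = 0.05, fisherAlpha = 0.01,
                             fit = NULL) {
  fis <- fisherHomoscedasticityTest(table, fisherAlpha)
  lof <- lackOfFitTest(table, fit = fit, alpha = alpha)
  man <- mandelTest(table, alpha)
  new("LinearityVerdict",
      fisherF = fis$F, fisherPass = fis$pass,
      lofF = lof$F, lofDf = lof$df, lofPass = lof$pass,
      mandelF = man$F, mandelDf = man$df, mandelPass = man$pass,
      alpha = alpha)
}

#' Back-calculate a hair concentration from a response ratio
#'
#' Inverts the calibration line and scales for extract dilution and sample
#' mass relative to the 50 mg reference mass used to build the calibrators.
#' Negative back-calculated values are returned as such (the censoring step
#' reports them as below the LOD); they are never silently clamped.
#'
#' @param fit a [CalibrationFit] with positive slope
#' @param responseRatio analyte area / internal standard area
#' @param dilutionFactor extract dilution factor (default 1)
#' @param sampleMass analyzed hair mass in mg (> 0)
#' @param referenceMass calibrator hair mass in mg (default 50)
#' @return concentration in pg/mg (vectorized over `responseRatio`)
#' @export
backCalculate <- function(fit, responseRatio, dilutionFactor = 1,
                          sampleMass = 50, referenceMass = 50) {
  stopifnot(is(fit, "CalibrationFit"))
  if (!fit@slope > 0) stop("invalid fit: slope must be > 0")
  if (!sampleMass > 0) stop("sampleMass must be > 0")
  dilutionFactor * (responseRatio - fit@intercept) / fit@slope *
    (referenceMass / sampleMass)
}

#' Choose between the low and extended calibration ranges
#'
#' Concentrations up to the top of the low curve (60 pg/mg by default) are
#' quantified on it; higher values up to the top of the extended curve
#' (300 pg/mg) on that one; anything beyond requires extract dilution and
#' re-analysis.
#'
#' @param estimate preliminary concentration estimate, pg/mg
#' @param lowCurve,highCurve [CalibrationFit]s whose `range` slots define
#'   the two working ranges
#' @return list with `choice` (`"low"`, `"high"` or `"dilution_required"`),
#'   `fit` (the chosen [CalibrationFit] or NULL) and `rationale`
#' @export
selectRange <- function(estimate, lowCurve, highCurve) {
  lowTop <- lowCurve@range[2]
  highTop <- highCurve@range[2]
  if (estimate <= lowTop)
    list(choice = "low", fit = lowCurve,
         rationale = sprintf("estimate %g <= %g pg/mg", estimate, lowTop))
  else if (estimate <= highTop)
    list(choice = "high", fit = highCurve,
         rationale = sprintf("estimate %g in (%g, %g] pg/mg", estimate,
                             lowTop, highTop))
  else
    list(choice = "dilution_required", fit = NULL,
         rationale = sprintf("estimate %g > %g pg/mg: dilute and re-analyze",
                             estimate, highTop))
}

#' Determine the limit of quantification
#'
#' The LOQ is the lowest concentration level whose intra-assay precision
#' (CV\%) and absolute relative bias are both within the threshold (20\% by
#' default). In practice this is the lowest calibration level when that
#' level qualifies.
#'
#' @param levels `data.frame` with columns `level` (pg/mg, ascending),
#'   `cv_percent` and `bias_percent`
#' @param threshold acceptance threshold in percent (default 20)
#' @return list with `loq` (pg/mg, NA when no level qualifies) and
#'   `defined`
#' @export
determineLoq <- function(levels, threshold = 20) {
  if (!nrow(levels)) stop("empty level table")
  need <- c("level", "cv_percent", "bias_percent")
  if (!all(need %in% names(levels)))
    stop("level table needs columns ", paste(need, collapse = ", "))
  levels <- levels[order(levels$level), ]
  ok <- levels$cv_percent <= threshold &
    abs(levels$bias_percent) <= threshold
  if (any(ok)) list(loq = min(levels$level[ok]), defined = TRUE)
  else list(loq = NA_real_, defined = FALSE)
}
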