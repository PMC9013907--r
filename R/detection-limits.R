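## Detection limits by the two routes: measured signal-to-noise, and the
## Hubaux-Vos prediction-band algorithm on the calibration line.

#' LOD from a signal-to-noise series
#'
#' The LOD is the lowest measured concentration whose S/N strictly exceeds
#' the threshold (3 by convention). No interpolation between measured
#' levels is performed; when no level qualifies the result is flagged
#' undetermined.
#'
#' @param series `data.frame` with columns `concentration` (pg/mg, > 0)
#'   and `snr`
#' @param threshold S/N threshold (default 3)
#' @return a [LodResult] with `method = "snr"`
#' @examples
#' lodFromSnr(data.frame(concentration = c(4, 6), snr = c(3.5, 9)))
#' @export
lodFromSnr <- function(series, threshold = 3) {
  if (!NROW(series)) stop("empty S/N series")
  if (!all(c("concentration", "snr") %in% names(series)))
    stop("series needs columns concentration, snr")
  if (any(series$concentration <= 0))
    stop("concentrations must be positive")
  ok <- series$snr > threshold
  if (any(ok))
    new("LodResult", method = "snr", lod = min(series$concentration[ok]),
        decisionLimit = NA_real_, alpha = NA_real_, beta = NA_real_,
        determined = TRUE)
  else
    new("LodResult", method = "snr", lod = NA_real_,
        decisionLimit = NA_real_, alpha = NA_real_, beta = NA_real_,
        determined = FALSE)
}

#' Hubaux-Vos detection limit from the calibration line
#'
#' The decision limit `x_C` is the concentration whose expected response
#' equals the upper one-sided (1 - alpha) prediction bound of a blank:
#' \deqn{y_C = a + t_{1-\alpha, n-2}\, s_{y/x}\sqrt{1 + 1/n + \bar x^2 / S_{xx}},
#'   \quad x_C = (y_C - a) / b.}
#' The detection limit `x_D` is the smallest concentration whose lower
#' one-sided (1 - beta) prediction bound exceeds `y_C`; because the band
#' half-width depends on `(x - \bar x)^2 / S_{xx}` there is no closed form
#' and `x_D` is found numerically (bisection to 1e-6 pg/mg). With a
#' noise-free calibration both limits are zero. Both bounds are one-sided:
#' detection is a one-sided decision.
#'
#' @param fit a [CalibrationFit] with positive slope and n >= 4
#' @param alpha false-positive rate (default 0.05)
#' @param beta false-negative rate (default 0.05)
#' @return a [LodResult] with `method = "hubaux_vos"`, carrying `lod`
#'   (`x_D`) and `decisionLimit` (`x_C`) in pg/mg
#' @examples
#' fit <- fitCalibration(simulateCalibration(CalibrationSimSpec()))
#' lodHubauxVos(fit)
#' @export
lodHubauxVos <- function(fit, alpha = 0.05, beta = 0.05) {
  stopifnot(is(fit, "CalibrationFit"))
  if (!fit@slope > 0) stop("invalid fit: slope must be > 0")
  if (fit@n < 4) stop("Hubaux-Vos requires n >= 4 calibration points")
  if (is.na(fit@residualSd)) stop("residual SD undefined")
  s <- fit@residualSd
  if (s == 0)
    return(new("LodResult", method = "hubaux_vos", lod = 0,
               decisionLimit = 0, alpha = alpha, beta = beta,
               determined = TRUE))
  n <- fit@n
  halfWidth <- function(x, t)
    t * s * sqrt(1 + 1 / n + (x - fit@meanX)^2 / fit@sxx)
  tA <- qt(1 - alpha, n - 2)
  tB <- qt(1 - beta, n - 2)
  yC <- fit@intercept + halfWidth(0, tA)
  xC <- (yC - fit@intercept) / fit@slope
  # lower (1 - beta) prediction bound at x, minus the decision level
  g <- function(x) fit@intercept + fit@slope * x - halfWidth(x, tB) - yC
  upper <- max(2 * xC, 1e-3)
  it <- 0
  while (g(upper) < 0 && it < 80) {
    upper <- upper * 2
    it <- it + 1
  }
  if (g(upper) < 0)
    stop("detection limit does not converge for this design")
  xD <- uniroot(g, c(xC, upper), tol = 1e-6)$root
  new("LodResult", method = "hubaux_vos", lod = xD, decisionLimit = xC,
      alpha = alpha, beta = beta, determined = TRUE)
}
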