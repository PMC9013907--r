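# shared builders for tests

# noise-free Gaussian peak trace on the quantifier transition
gaussTrace <- function(rt = 30, height = 1000, sigma = 2, duration = 60,
                       dt = 0.05, baseline = 0, transition = NULL) {
  transition <- transition %||% quantifier(etgSrmMethod())
  t <- seq(0, duration, by = dt)
  SRMTrace(transition, t, baseline + height * exp(-(t - rt)^2 / (2 * sigma^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# calibration table straight from vectors
calTable <- function(x, y) {
  data.frame(nominal_pg_per_mg = x, response_ratio = y)
}

# a synthetic PeakResult with a given area
peakWithArea <- function(area) PeakResult(30, max(area, 0), area)
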