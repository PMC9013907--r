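## Synthetic-data generators. Noise-free generators are exactly their
## deterministic mean models; a fixed seed gives bit-identical output.

#' Simulate SRM chromatogram traces
#'
#' Generates one [SRMTrace] per transition named in the spec: a constant
#' baseline plus Gaussian peaks, i.i.d. Gaussian intensity noise, and an
#' optional interference peak on a single transition.
#'
#' @param spec a [TraceSpec()]
#' @param method the [SRMMethod] whose transition labels resolve the spec's
#'   transition identifiers; defaults to [etgSrmMethod()]
#' @return named list of [SRMTrace] objects, one per transition, each of
#'   length `floor(duration / samplingInterval) + 1`
#' @examples
#' spec <- TraceSpec("405>359", duration = 60, samplingInterval = 0.5,
#'                   peaks = data.frame(transition = "405>359", rt = 30,
#'                                      height = 1000, sigma = 2))
#' tr <- simulateTraces(spec)[["405>359"]]
#' max(tr@intensities)
#' @export
simulateTraces <- function(spec, method = etgSrmMethod()) {
  stopifnot(is(spec, "TraceSpec"))
  validObject(spec)
  labels <- vapply(transitions(method), transitionLabel, character(1))
  unknown <- setdiff(spec@transitions, labels)
  if (length(unknown))
    stop("transitions: unknown transition id(s) ",
         paste(unknown, collapse = ", "), "; method provides ",
         paste(labels, collapse = ", "))
  times <- seq(0, spec@duration, by = spec@samplingInterval)
  gauss <- function(rt, height, sigma)
    height * exp(-(times - rt)^2 / (2 * sigma^2))
  withSeed(spec@seed, {
    out <- lapply(spec@transitions, function(id) {
      y <- rep(spec@baselineLevel, length(times))
      pk <- spec@peaks[spec@peaks$transition == id, , drop = FALSE]
      for (i in seq_len(nrow(pk)))
        y <- y + gauss(pk$rt[i], pk$height[i], pk$sigma[i])
      intf <- spec@interference
      intf <- intf[intf$transition == id, , drop = FALSE]
      for (i in seq_len(nrow(intf)))
        y <- y + gauss(intf$rt[i], intf$height[i], intf$sigma[i])
      if (spec@noiseSd > 0)
        y <- y + rnorm(length(times), 0, spec@noiseSd)
      SRMTrace(transitions(method)[[match(id, labels)]], times, y)
    })
    names(out) <- spec@transitions
    out
  })
}

#' Simulate a calibration table
#'
#' @param spec a [CalibrationSimSpec()]
#' @return `data.frame` with columns `nominal_pg_per_mg`, `response_ratio`
#'   and `replicate`; the expected ratio at level x is
#'   `intercept + slope * x + curvature * x^2`
#' @examples
#' head(simulateCalibration(CalibrationSimSpec(noiseParam = 0)))
#' @export
simulateCalibration <- function(spec) {
  stopifnot(is(spec, "CalibrationSimSpec"))
  validObject(spec)
  x <- rep(spec@levels, each = spec@replicates)
  mu <- spec@intercept + spec@slope * x + spec@curvature * x^2
  withSeed(spec@seed, {
    eps <- if (spec@noiseParam > 0) {
      sdv <- switch(spec@noiseModel,
                    constant_sd = rep(spec@noiseParam, length(mu)),
                    proportional_cv = spec@noiseParam * abs(mu))
      rnorm(length(mu), 0, sdv)
    } else 0
    data.frame(nominal_pg_per_mg = x, response_ratio = mu + eps,
               replicate = rep(seq_len(spec@replicates),
                               times = length(spec@levels)))
  })
}

# coded 2^k design in standard Yates order (a varies fastest);
# run labels are the letters of the factors set high, "0" when none
yatesDesign <- function(k) {
  runs <- 0:(2^k - 1)
  coded <- vapply(seq_len(k), function(j)
    ifelse(bitwAnd(runs, bitwShiftL(1L, j - 1L)) > 0, 1L, -1L),
    integer(length(runs)))
  coded <- matrix(coded, nrow = length(runs),
                  dimnames = list(NULL, letters[seq_len(k)]))
  lab <- apply(coded, 1, function(r) {
    hi <- letters[seq_len(k)][r > 0]
    if (length(hi)) paste(hi, collapse = "") else "0"
  })
  data.frame(run_label = lab, coded, stringsAsFactors = FALSE)
}

# canonical effect labels up to maxOrder, grouped by order
effectLabels <- function(k, maxOrder = k) {
  f <- letters[seq_len(k)]
  unlist(lapply(seq_len(maxOrder), function(o)
    apply(utils::combn(f, o), 2, paste, collapse = "")))
}

#' Simulate a replicated 2^k factorial experiment
#'
#' @param spec a [FactorialSimSpec()]
#' @return `data.frame` in standard Yates run order within each block, with
#'   columns `block`, `run_label`, one coded-level (-1/+1) column per factor
#'   letter, and `response_pg_per_mg`
#' @examples
#' simulateFactorial(FactorialSimSpec(noiseSd = 0, replicateBlocks = 1))
#' @export
simulateFactorial <- function(spec) {
  stopifnot(is(spec, "FactorialSimSpec"))
  validObject(spec)
  des <- yatesDesign(spec@k)
  mu <- rep(spec@grandMean, nrow(des))
  for (lab in names(spec@trueEffects)) {
    sgn <- apply(des[, strsplit(lab, "")[[1]], drop = FALSE], 1, prod)
    mu <- mu + spec@trueEffects[[lab]] / 2 * sgn
  }
  withSeed(spec@seed, {
    blocks <- lapply(seq_len(spec@replicateBlocks), function(b) {
      y <- mu
      if (spec@noiseSd > 0) y <- y + rnorm(length(mu), 0, spec@noiseSd)
      cbind(data.frame(block = b), des, data.frame(response_pg_per_mg = y))
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a drinking cohort with censored EtG results
#'
#' Concentrations are log-normal per declared class and censored at the
#' method's LOD and LOQ; simple subject covariates (age, gender, hair
#' length, cosmetic treatment) are attached for report plumbing.
#'
#' @param spec a [CohortSimSpec()]
#' @return `data.frame` with columns `subject_id`, `age`, `gender`,
#'   `hair_length_cm`, `cosmetic_treatment`, `drinking_class` (ordered
#'   factor), `etg_pg_per_mg` (NA when censored) and `etg_status`
#' @examples
#' table(simulateCohort(CohortSimSpec())$drinking_class)
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSimSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    per <- lapply(names(spec@categorySizes), function(cl) {
      n <- spec@categorySizes[[cl]]
      if (n == 0) return(NULL)
      p <- spec@lognormalParams[spec@lognormalParams$class == cl, ][1, ]
      conc <- if (p$median <= 0) rep(0, n)
              else rlnorm(n, meanlog = log(p$median), sdlog = log(p$gsd))
      data.frame(
        age = sample(18:65, n, replace = TRUE),
        gender = sample(c("M", "F"), n, replace = TRUE),
        hair_length_cm = sample(3:6, n, replace = TRUE),
        cosmetic_treatment = sample(c(FALSE, TRUE), n, replace = TRUE,
                                    prob = c(0.8, 0.2)),
        drinking_class = cl,
        concentration = conc
      )
    })
    out <- do.call(rbind, per)
    out$subject_id <- sprintf("S%03d", seq_len(nrow(out)))
    cen <- censorConcentration(out$concentration, spec@lod, spec@loq)
    out$etg_pg_per_mg <- cen$etg_pg_per_mg
    out$etg_status <- cen$etg_status
    out$concentration <- NULL
    out$drinking_class <- factor(out$drinking_class,
                                 levels = drinkingClasses(), ordered = TRUE)
    rownames(out) <- NULL
    out[, c("subject_id", "age", "gender", "hair_length_cm",
            "cosmetic_treatment", "drinking_class", "etg_pg_per_mg",
            "etg_status")]
  })
}
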