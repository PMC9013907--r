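## Central S4 classes. Validity methods enforce the domain invariants so
## that downstream arithmetic can assume well-formed objects.

## ---------------------------------------------------------------------------
## SRM method description

#' @rdname Transition
#' @export
setClass("Transition",
  slots = c(
    precursorMz = "numeric",
    productMz = "numeric",
    collisionEnergy = "numeric",
    role = "character"
  )
)

setValidity("Transition", function(object) {
  msg <- character()
  if (length(object@precursorMz) != 1 || length(object@productMz) != 1 ||
      length(object@collisionEnergy) != 1 || length(object@role) != 1)
    msg <- c(msg, "all slots must have length 1")
  else {
    if (!object@productMz < object@precursorMz)
      msg <- c(msg, "productMz: must be smaller than precursorMz")
    if (!object@collisionEnergy > 0)
      msg <- c(msg, "collisionEnergy: must be > 0")
    if (!object@role %in% c("quantifier", "qualifier", "internal_standard"))
      msg <- c(msg, "role: must be quantifier, qualifier or internal_standard")
  }
  if (length(msg)) msg else TRUE
})

#' SRM transitions and acquisition methods
#'
#' A `Transition` is a single precursor-to-product SRM channel; an
#' `SRMMethod` bundles the transitions acquired for one analyte, with
#' exactly one quantifier, exactly one isotopically labelled
#' internal-standard transition, and at least one qualifier used for
#' identity confirmation via ion ratios.
#'
#' @param precursorMz,productMz precursor and product ion m/z (Th)
#' @param collisionEnergy collision energy in volts
#' @param role one of `"quantifier"`, `"qualifier"`, `"internal_standard"`
#' @return `Transition()` a `Transition`; `SRMMethod()` an `SRMMethod`.
#' @examples
#' Transition(405, 359, 10, "quantifier")
#' etgSrmMethod()
#' @aliases Transition SRMMethod
#' @export
Transition <- function(precursorMz, productMz, collisionEnergy = 10,
                       role = "qualifier") {
  new("Transition", precursorMz = as.numeric(precursorMz),
      productMz = as.numeric(productMz),
      collisionEnergy = as.numeric(collisionEnergy), role = role)
}

#' @rdname Transition
#' @export
setClass("SRMMethod", slots = c(transitions = "list"))

setValidity("SRMMethod", function(object) {
  if (!all(vapply(object@transitions, is, logical(1), "Transition")))
    return("transitions: all elements must be Transition objects")
  roles <- vapply(object@transitions, function(t) t@role, character(1))
  msg <- character()
  if (sum(roles == "quantifier") != 1)
    msg <- c(msg, "transitions: exactly one quantifier required")
  if (sum(roles == "internal_standard") != 1)
    msg <- c(msg, "transitions: exactly one internal_standard required")
  if (sum(roles == "qualifier") < 1)
    msg <- c(msg, "transitions: at least one qualifier required")
  if (length(msg)) msg else TRUE
})

#' @rdname Transition
#' @param ... `Transition` objects
#' @export
SRMMethod <- function(...) {
  new("SRMMethod", transitions = list(...))
}

#' @describeIn Transition the EtG-TMS acquisition scheme: m/z 405 -> 359
#'   quantifier, 410 -> 359 internal standard (EtG-D5), 405 -> 331 and
#'   405 -> 287 qualifiers, all at 10 V collision energy.
#' @export
etgSrmMethod <- function() {
  SRMMethod(
    Transition(405, 359, 10, "quantifier"),
    Transition(410, 359, 10, "internal_standard"),
    Transition(405, 331, 10, "qualifier"),
    Transition(405, 287, 10, "qualifier")
  )
}

## ---------------------------------------------------------------------------
## Chromatogram trace and integrated peak

#' SRM chromatogram trace
#'
#' Intensity versus time for a single SRM transition. Times must be strictly
#' increasing and the same length as the intensities.
#'
#' @param transition a [Transition()]
#' @param times acquisition times in seconds, strictly increasing
#' @param intensities ion counts, same length as `times`
#' @return an `SRMTrace`
#' @export
setClass("SRMTrace",
  slots = c(transition = "Transition", times = "numeric",
            intensities = "numeric")
)

setValidity("SRMTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@intensities))
    msg <- c(msg, "times/intensities: lengths differ")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times: must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname SRMTrace-class
#' @export
SRMTrace <- function(transition, times, intensities) {
  new("SRMTrace", transition = transition, times = as.numeric(times),
      intensities = as.numeric(intensities))
}

#' Integrated chromatographic peak
#'
#' Result of baseline-subtracted peak integration: apex retention time,
#' height and area above baseline, the RMS baseline noise used for the
#' signal-to-noise ratio, and `snr = height / noiseRms`.
#'
#' @param retentionTime apex time, seconds
#' @param height counts above baseline
#' @param area counts x seconds, floored at zero
#' @param noiseRms RMS baseline noise in counts (`NA` when not supplied)
#' @param snr dimensionless signal-to-noise ratio
#' @return a `PeakResult`
#' @export
setClass("PeakResult",
  slots = c(retentionTime = "numeric", height = "numeric", area = "numeric",
            noiseRms = "numeric", snr = "numeric")
)

setValidity("PeakResult", function(object) {
  msg <- character()
  if (object@height < 0) msg <- c(msg, "height: must be >= 0")
  if (object@area < 0) msg <- c(msg, "area: must be >= 0")
  if (!is.na(object@noiseRms) && object@noiseRms > 0 && !is.na(object@snr) &&
      abs(object@snr - object@height / object@noiseRms) > 1e-8 * max(1, object@snr))
    msg <- c(msg, "snr: must equal height / noiseRms")
  if (length(msg)) msg else TRUE
})

#' @rdname PeakResult-class
#' @export
PeakResult <- function(retentionTime, height, area, noiseRms = NA_real_,
                       snr = NA_real_) {
  new("PeakResult", retentionTime = retentionTime, height = height,
      area = area, noiseRms = noiseRms, snr = snr)
}

## ---------------------------------------------------------------------------
## Calibration

#' Unweighted linear calibration fit
#'
#' Ordinary least-squares fit of the response ratio (analyte area / internal
#' standard area) on nominal concentration, retaining the quantities needed
#' for prediction-band detection limits: residual standard deviation
#' \eqn{s_{y/x}}, mean concentration \eqn{\bar x}, and
#' \eqn{S_{xx} = \sum (x_i - \bar x)^2}.
#'
#' @seealso [fitCalibration()], [lodHubauxVos()]
#' @export
setClass("CalibrationFit",
  slots = c(slope = "numeric", intercept = "numeric", residualSd = "numeric",
            n = "integer", meanX = "numeric", sxx = "numeric",
            rSquared = "numeric", range = "numeric")
)

setValidity("CalibrationFit", function(object) {
  msg <- character()
  if (object@n < 3) msg <- c(msg, "n: at least 3 points required")
  if (!object@sxx > 0) msg <- c(msg, "sxx: must be > 0")
  if (object@residualSd < 0) msg <- c(msg, "residualSd: must be >= 0")
  if (length(object@range) != 2 || object@range[1] > object@range[2])
    msg <- c(msg, "range: must be (low, high) with low <= high")
  if (length(msg)) msg else TRUE
})

#' Linearity test verdicts for a calibration design
#'
#' Bundles the Fisher homoscedasticity F test on the extreme calibration
#' levels, the replicate-based lack-of-fit F test, and the Mandel
#' linear-vs-quadratic F test, each with its pass/fail decision at the
#' stated significance level.
#'
#' @seealso [linearityVerdict()]
#' @export
setClass("LinearityVerdict",
  slots = c(fisherF = "numeric", fisherPass = "logical",
            lofF = "numeric", lofDf = "integer", lofPass = "logical",
            mandelF = "numeric", mandelDf = "integer", mandelPass = "logical",
            alpha = "numeric")
)

setValidity("LinearityVerdict", function(object) {
  msg <- character()
  fs <- c(object@fisherF, object@lofF, object@mandelF)
  if (any(!is.na(fs) & fs < 0)) msg <- c(msg, "F statistics must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Detection limits

#' Detection-limit estimate
#'
#' LOD estimated either from measured signal-to-noise ratios (`method =
#' "snr"`) or from the calibration line's one-sided prediction bands by the
#' Hubaux-Vos algorithm (`method = "hubaux_vos"`, which also carries the
#' decision limit controlling the false-positive rate alpha, with the
#' detection limit additionally controlling the false-negative rate beta).
#'
#' @seealso [lodFromSnr()], [lodHubauxVos()]
#' @export
setClass("LodResult",
  slots = c(method = "character", lod = "numeric", decisionLimit = "numeric",
            alpha = "numeric", beta = "numeric", determined = "logical")
)

setValidity("LodResult", function(object) {
  msg <- character()
  if (!object@method %in% c("snr", "hubaux_vos"))
    msg <- c(msg, "method: must be 'snr' or 'hubaux_vos'")
  if (!is.na(object@lod) && object@lod < 0)
    msg <- c(msg, "lod: must be >= 0")
  if (!is.na(object@lod) && !is.na(object@decisionLimit) &&
      object@lod < object@decisionLimit - 1e-9)
    msg <- c(msg, "lod: must be >= decisionLimit")
  if (!is.na(object@decisionLimit) && object@decisionLimit < 0)
    msg <- c(msg, "decisionLimit: must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Validation report

#' Full method-validation report
#'
#' Container assembled by [assembleReport()]: calibration fit, linearity
#' verdicts, detection limits, LOQ, per-level precision/trueness, the blank
#' interference check, the acceptance limits applied, and the overall
#' verdict with failure reasons.
#'
#' @export
setClass("ValidationReport",
  slots = c(fit = "CalibrationFit", linearity = "LinearityVerdict",
            lodResults = "list", loq = "numeric", loqDefined = "logical",
            qc = "data.frame", interference = "list", limits = "list",
            overallPass = "logical", reasons = "character")
)

## ---------------------------------------------------------------------------
## Simulation specifications

#' Specification for simulated SRM chromatogram traces
#'
#' Defines the signal model for synthetic SRM traces: Gaussian peaks over a
#' constant baseline with i.i.d. Gaussian intensity noise, optionally with a
#' co-eluting interference peak on one transition (the failure mode observed
#' on a qualifier channel for pulverized hair samples).
#'
#' @param transitions transition labels (e.g. `"405>359"`), resolved against
#'   an [SRMMethod] at simulation time
#' @param duration trace duration, seconds
#' @param samplingInterval sampling interval, seconds (> 0)
#' @param peaks `data.frame` with columns `transition`, `rt` (s), `height`
#'   (counts), `sigma` (s): one Gaussian peak per row
#' @param baselineLevel constant baseline, counts
#' @param noiseSd SD of i.i.d. Gaussian intensity noise, counts (>= 0)
#' @param interference optional single-row `data.frame` with the same
#'   columns as `peaks`, added on top of the declared peaks
#' @param seed integer RNG seed
#' @return a `TraceSpec`
#' @seealso [simulateTraces()]
#' @export
setClass("TraceSpec",
  slots = c(transitions = "character", duration = "numeric",
            samplingInterval = "numeric", peaks = "data.frame",
            baselineLevel = "numeric", noiseSd = "numeric",
            interference = "data.frame", seed = "numeric")
)

.peakCols <- c("transition", "rt", "height", "sigma")

setValidity("TraceSpec", function(object) {
  msg <- character()
  if (!object@samplingInterval > 0)
    msg <- c(msg, "samplingInterval: must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd: must be >= 0")
  for (nm in c("peaks", "interference")) {
    df <- slot(object, nm)
    if (nrow(df)) {
      if (!all(.peakCols %in% names(df))) {
        msg <- c(msg, paste0(nm, ": needs columns ",
                             paste(.peakCols, collapse = ", ")))
        next
      }
      if (any(df$height < 0)) msg <- c(msg, paste0(nm, ": heights must be >= 0"))
      if (any(df$rt < 0 | df$rt > object@duration))
        msg <- c(msg, paste0(nm, ": retention times must lie in [0, duration]"))
      if (any(df$sigma <= 0)) msg <- c(msg, paste0(nm, ": sigma must be > 0"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname TraceSpec-class
#' @export
TraceSpec <- function(transitions, duration = 60, samplingInterval = 0.1,
                      peaks = data.frame(), baselineLevel = 0, noiseSd = 0,
                      interference = NULL, seed = 1L) {
  if (is.null(interference))
    interference <- data.frame(transition = character(), rt = numeric(),
                               height = numeric(), sigma = numeric())
  new("TraceSpec", transitions = transitions, duration = duration,
      samplingInterval = samplingInterval, peaks = peaks,
      baselineLevel = baselineLevel, noiseSd = noiseSd,
      interference = interference, seed = as.numeric(seed))
}

#' Specification for simulated calibration tables
#'
#' Response ratios linear (optionally quadratic) in concentration with
#' configurable homoscedastic (`constant_sd`) or heteroscedastic
#' (`proportional_cv`) Gaussian noise. Defaults are the working calibration
#' of the assay: levels 6, 10, 20, 30 and 60 pg/mg in triplicate.
#'
#' @param levels concentrations in pg EtG per mg hair, strictly positive and
#'   strictly increasing
#' @param replicates replicates per level (>= 1)
#' @param slope response-ratio per (pg/mg)
#' @param intercept response-ratio at zero concentration
#' @param noiseModel `"constant_sd"` or `"proportional_cv"`
#' @param noiseParam SD (ratio units) or CV (fraction), >= 0
#' @param curvature coefficient of concentration^2, default 0 (linear)
#' @param seed integer RNG seed
#' @return a `CalibrationSimSpec`
#' @seealso [simulateCalibration()]
#' @export
setClass("CalibrationSimSpec",
  slots = c(levels = "numeric", replicates = "integer", slope = "numeric",
            intercept = "numeric", noiseModel = "character",
            noiseParam = "numeric", curvature = "numeric", seed = "numeric")
)

setValidity("CalibrationSimSpec", function(object) {
  msg <- character()
  if (any(object@levels <= 0))
    msg <- c(msg, "levels: must be strictly positive")
  if (length(object@levels) > 1 && any(diff(object@levels) <= 0))
    msg <- c(msg, "levels: must be strictly increasing")
  if (object@replicates < 1) msg <- c(msg, "replicates: must be >= 1")
  if (object@noiseParam < 0) msg <- c(msg, "noiseParam: must be >= 0")
  if (!object@noiseModel %in% c("constant_sd", "proportional_cv"))
    msg <- c(msg, "noiseModel: must be 'constant_sd' or 'proportional_cv'")
  if (length(msg)) msg else TRUE
})

#' @rdname CalibrationSimSpec-class
#' @export
CalibrationSimSpec <- function(levels = c(6, 10, 20, 30, 60), replicates = 3,
                               slope = 0.01, intercept = 0,
                               noiseModel = "constant_sd", noiseParam = 0.01,
                               curvature = 0, seed = 1L) {
  new("CalibrationSimSpec", levels = as.numeric(levels),
      replicates = as.integer(replicates), slope = slope,
      intercept = intercept, noiseModel = noiseModel,
      noiseParam = noiseParam, curvature = curvature,
      seed = as.numeric(seed))
}

#' Specification for simulated 2^k factorial pretreatment experiments
#'
#' Generates replicated full-factorial response tables in standard Yates run
#' order. True effects follow the mean(high) - mean(low) convention, so a
#' run's expected response is the grand mean plus half of each specified
#' effect times the product of its coded levels. Defaults reproduce the
#' hair-pretreatment experiment: factors a (washing), b (incubation), c
#' (shredding), three donor blocks.
#'
#' @param k number of two-level factors (>= 2)
#' @param trueEffects named numeric vector of effect sizes in pg/mg; names
#'   are nonempty subsets of the first `k` factor letters (e.g. `"a"`,
#'   `"bc"`)
#' @param grandMean grand mean response, pg/mg
#' @param replicateBlocks number of replicate blocks (donors)
#' @param noiseSd run-to-run Gaussian noise SD, pg/mg (>= 0)
#' @param seed integer RNG seed
#' @return a `FactorialSimSpec`
#' @seealso [simulateFactorial()], [estimateEffects()]
#' @export
setClass("FactorialSimSpec",
  slots = c(k = "integer", trueEffects = "numeric", grandMean = "numeric",
            replicateBlocks = "integer", noiseSd = "numeric",
            seed = "numeric")
)

setValidity("FactorialSimSpec", function(object) {
  msg <- character()
  if (object@k < 2) msg <- c(msg, "k: must be >= 2")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd: must be >= 0")
  if (object@replicateBlocks < 1)
    msg <- c(msg, "replicateBlocks: must be >= 1")
  labs <- names(object@trueEffects)
  if (length(object@trueEffects) && is.null(labs))
    msg <- c(msg, "trueEffects: must be named by effect label")
  ok <- vapply(labs %||% character(), function(l) {
    ch <- strsplit(l, "")[[1]]
    nchar(l) > 0 && !anyDuplicated(ch) && all(ch %in% letters[seq_len(object@k)])
  }, logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, paste0("trueEffects: unknown effect label(s) ",
                         paste(labs[!ok], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname FactorialSimSpec-class
#' @export
FactorialSimSpec <- function(k = 3,
                             trueEffects = c(a = 3.55, b = 34.95, c = 66.95,
                                             ab = 6.5, ac = -11.7, bc = -36),
                             grandMean = 147.3, replicateBlocks = 3,
                             noiseSd = 8, seed = 1L) {
  new("FactorialSimSpec", k = as.integer(k), trueEffects = trueEffects,
      grandMean = grandMean, replicateBlocks = as.integer(replicateBlocks),
      noiseSd = noiseSd, seed = as.numeric(seed))
}

#' Specification for simulated drinking cohorts
#'
#' Per drinking class, EtG hair concentrations are drawn from a log-normal
#' distribution (strictly positive, right-skewed) and then censored at the
#' method's LOD and LOQ. A class median of 0 produces all-censored records.
#' Defaults mirror the study cohort: 6 teetotalers, 6 light, 4 social,
#' 6 moderate and 3 heavy drinkers, LOD 4 and LOQ 6 pg/mg.
#'
#' @param categorySizes named integer vector of subjects per class; names
#'   from `Teetotal`, `Light`, `Social`, `Moderate`, `Heavy`
#' @param lognormalParams `data.frame` with columns `class`, `median`
#'   (pg/mg) and `gsd` (geometric SD, > 1)
#' @param lod,loq censoring limits in pg/mg, `0 < lod <= loq`
#' @param seed integer RNG seed
#' @return a `CohortSimSpec`
#' @seealso [simulateCohort()]
#' @export
setClass("CohortSimSpec",
  slots = c(categorySizes = "integer", lognormalParams = "data.frame",
            lod = "numeric", loq = "numeric", seed = "numeric")
)

setValidity("CohortSimSpec", function(object) {
  msg <- character()
  if (any(object@categorySizes < 0))
    msg <- c(msg, "categorySizes: counts must be >= 0")
  if (!all(names(object@categorySizes) %in% drinkingClasses()))
    msg <- c(msg, paste0("categorySizes: classes must be among ",
                         paste(drinkingClasses(), collapse = ", ")))
  if (!(object@lod > 0 && object@lod <= object@loq))
    msg <- c(msg, "lod/loq: need 0 < lod <= loq")
  lp <- object@lognormalParams
  if (!all(c("class", "median", "gsd") %in% names(lp)))
    msg <- c(msg, "lognormalParams: needs columns class, median, gsd")
  else {
    if (any(lp$median < 0)) msg <- c(msg, "lognormalParams: medians must be >= 0")
    if (!all(names(object@categorySizes) %in% lp$class))
      msg <- c(msg, "lognormalParams: missing parameters for some class")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CohortSimSpec-class
#' @export
CohortSimSpec <- function(categorySizes = c(Teetotal = 6, Light = 6,
                                            Social = 4, Moderate = 6,
                                            Heavy = 3),
                          lognormalParams = data.frame(
                            class = c("Teetotal", "Light", "Social",
                                      "Moderate", "Heavy"),
                            median = c(0.5, 2, 15, 25, 120),
                            gsd = c(2, 2, 1.4, 2.5, 1.6)),
                          lod = 4, loq = 6, seed = 1L) {
  new("CohortSimSpec",
      categorySizes = setNames(as.integer(categorySizes),
                               names(categorySizes)),
      lognormalParams = lognormalParams, lod = lod, loq = loq,
      seed = as.numeric(seed))
}
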