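## SRM trace processing: peak integration, RMS noise, ion-ratio checks.

#' Integrate a chromatographic peak
#'
#' Baseline-subtracted peak integration over an explicit, caller-supplied
#' retention-time window. By default the baseline is a straight line
#' interpolated between the medians of the first and last `edgePoints`
#' samples of the window; a known baseline can be supplied instead (needed
#' e.g. when a window edge sits on the peak itself). Height is the maximum
#' of the baseline-subtracted signal, area its trapezoidal integral floored
#' at zero. Both are invariant under adding a constant to the whole trace.
#'
#' @param trace an [SRMTrace]
#' @param window `c(t_start, t_end)` in seconds; must lie inside the trace
#'   and contain at least 5 samples
#' @param noiseRms RMS baseline noise (counts) used to compute the S/N
#'   ratio; see [estimateNoiseRms()]
#' @param baseline `"edges"` (default) for edge-median interpolation, or a
#'   numeric baseline level (scalar or one value per window sample)
#' @param edgePoints samples per window edge used for the baseline medians
#' @return a [PeakResult]
#' @examples
#' spec <- TraceSpec("405>359", duration = 60, samplingInterval = 0.1,
#'                   peaks = data.frame(transition = "405>359", rt = 30,
#'                                      height = 1000, sigma = 2))
#' tr <- simulateTraces(spec)[["405>359"]]
#' integratePeak(tr, c(20, 40))
#' @export
integratePeak <- function(trace, window, noiseRms = NA_real_,
                          baseline = "edges", edgePoints = 3L) {
  stopifnot(is(trace, "SRMTrace"), length(window) == 2)
  t <- trace@times
  if (window[1] < t[1] || window[2] > t[length(t)])
    stop(sprintf("integration window [%g, %g] outside trace time range [%g, %g]",
                 window[1], window[2], t[1], t[length(t)]))
  idx <- which(t >= window[1] & t <= window[2])
  if (length(idx) < 5)
    stop("integration window contains fewer than 5 samples; ",
         "widen the window or increase the sampling rate")
  tw <- t[idx]
  yw <- trace@intensities[idx]
  nw <- length(idx)
  if (is.character(baseline) && identical(baseline, "edges")) {
    e <- min(as.integer(edgePoints), floor(nw / 2))
    li <- seq_len(e)
    ri <- seq(nw - e + 1, nw)
    yl <- median(yw[li]); yr <- median(yw[ri])
    tl <- mean(tw[li]); tr_ <- mean(tw[ri])
    base <- yl + (yr - yl) * (tw - tl) / (tr_ - tl)
  } else if (is.numeric(baseline)) {
    base <- rep_len(baseline, nw)
  } else {
    stop("baseline: must be \"edges\" or numeric")
  }
  s <- yw - base
  height <- max(max(s), 0)
  rt <- tw[which.max(s)]
  area <- max(trapezoid(tw, s), 0)
  snr <- if (!is.na(noiseRms) && noiseRms > 0) height / noiseRms else NA_real_
  PeakResult(retentionTime = rt, height = height, area = area,
             noiseRms = noiseRms, snr = snr)
}

#' Estimate RMS baseline noise
#'
#' Root-mean-square of the residuals after removing a linear trend fitted to
#' a peak-free region of the trace. This is the reproducible counterpart of
#' vendor "auto-RMS" noise estimators and feeds the S/N-based detection
#' limit.
#'
#' @param trace an [SRMTrace]
#' @param region `c(t_start, t_end)` in seconds, containing at least 20
#'   samples
#' @param peakWindows list of declared peak windows (each `c(start, end)`);
#'   the region must not overlap any of them
#' @return RMS noise in counts
#' @export
estimateNoiseRms <- function(trace, region, peakWindows = list()) {
  stopifnot(is(trace, "SRMTrace"), length(region) == 2)
  for (w in peakWindows)
    if (windowsOverlap(region, w))
      stop(sprintf("noise region [%g, %g] overlaps declared peak window [%g, %g]",
                   region[1], region[2], w[1], w[2]))
  idx <- which(trace@times >= region[1] & trace@times <= region[2])
  if (length(idx) < 20)
    stop("noise region must contain at least 20 samples")
  tw <- trace@times[idx]
  yw <- trace@intensities[idx]
  r <- resid(lm(yw ~ tw))
  sqrt(mean(r^2))
}

#' Check qualifier ion ratios against reference ratios
#'
#' Analyte identity is confirmed when every qualifier's area, expressed as a
#' fraction of the quantifier area, lies within a relative tolerance of its
#' reference ratio. A qualifier with no integrated peak is reported
#' non-compliant with reason `"absent"`. A strong co-eluting interference on
#' one qualifier channel inflates only that qualifier's ratio and fails only
#' that qualifier.
#'
#' @param peaks named list of [PeakResult]s; names are transition labels
#' @param referenceRatios named numeric vector, qualifier label ->
#'   reference fraction of quantifier area (see [referenceIonRatios()])
#' @param tolerance relative tolerance (default 0.2, i.e. +/- 20\%)
#' @param quantifier label of the quantifier transition
#' @return list with elements `qualifiers` (data.frame: `qualifier`,
#'   `observed_ratio`, `reference_ratio`, `compliant`, `reason`) and `pass`
#'   (TRUE iff all qualifiers comply)
#' @export
checkIonRatios <- function(peaks, referenceRatios, tolerance = 0.2,
                           quantifier = "405>359") {
  if (!quantifier %in% names(peaks))
    stop("quantifier peak '", quantifier, "' missing")
  qArea <- peaks[[quantifier]]@area
  if (!qArea > 0)
    stop("quantifier peak area must be > 0")
  rows <- lapply(names(referenceRatios), function(ql) {
    ref <- referenceRatios[[ql]]
    if (!ql %in% names(peaks) || is.na(peaks[[ql]]@area))
      return(data.frame(qualifier = ql, observed_ratio = NA_real_,
                        reference_ratio = ref, compliant = FALSE,
                        reason = "absent"))
    obs <- peaks[[ql]]@area / qArea
    ok <- abs(obs - ref) <= tolerance * ref
    data.frame(qualifier = ql, observed_ratio = obs, reference_ratio = ref,
               compliant = ok,
               reason = if (ok) "" else "outside tolerance")
  })
  df <- do.call(rbind, rows)
  list(qualifiers = df, pass = all(df$compliant))
}

#' Learn reference ion ratios from calibration standards
#'
#' The reference ratio of each qualifier is the mean of its observed
#' area fraction of the quantifier across a set of standards.
#'
#' @param standards list of named peak lists (one per standard), as passed
#'   to [checkIonRatios()]
#' @param quantifier label of the quantifier transition
#' @return named numeric vector of reference ratios
#' @export
referenceIonRatios <- function(standards, quantifier = "405>359") {
  quals <- setdiff(unique(unlist(lapply(standards, names))), quantifier)
  vapply(quals, function(ql) {
    mean(vapply(standards, function(p) p[[ql]]@area / p[[quantifier]]@area,
                numeric(1)))
  }, numeric(1))
}
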