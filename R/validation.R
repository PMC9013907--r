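## Precision/trueness statistics, the blank interference check, and
## assembly of the full validation report.

#' Precision and trueness at a QC level
#'
#' Sample statistics (n - 1 denominator) of replicate measurements at one
#' nominal concentration. Intra-day estimates use a single day's replicates
#' (n >= 3); inter-day estimates pool all measurements across >= 2 days
#' as a single sample. RSD and bias are returned unrounded; rounding to the
#' printed precision happens only at the report/serialization layer.
#'
#' @param values measured concentrations, pg/mg (> 0)
#' @param nominal nominal concentration, pg/mg
#' @param day optional day identifier per measurement
#' @param scope `"intra_day"` or `"inter_day"`
#' @return list with `mean`, `sd`, `rsd_percent`, `bias_percent` (signed)
#'   and `n`
#' @examples
#' precisionTrueness(c(19.9, 17.2, 22.1), nominal = 20, scope = "intra_day")
#' @export
precisionTrueness <- function(values, nominal,
                              scope = c("intra_day", "inter_day"),
                              day = NULL) {
  scope <- match.arg(scope)
  if (any(values <= 0)) stop("measurements must be > 0")
  if (scope == "intra_day") {
    if (!is.null(day) && length(unique(day)) > 1)
      stop("intra-day precision must use measurements from a single day")
    if (length(values) < 3)
      stop("intra-day precision requires >= 3 replicates")
  } else {
    if (is.null(day))
      stop("inter-day precision requires day identifiers")
    if (length(unique(day)) < 2)
      stop("inter-day precision requires >= 2 distinct days")
  }
  m <- mean(values)
  s <- sd(values)
  list(mean = m, sd = s, rsd_percent = rsdPercent(m, s),
       bias_percent = biasPercent(m, nominal), n = length(values))
}

#' Blank interference check
#'
#' Verifies that blank hair samples (teetotaler hair, untreated or dyed)
#' show no apparent analyte signal: for every blank, the back-calculated
#' apparent concentration in the quantifier retention window must stay
#' below the LOD. Interference confined to a qualifier channel does not
#' fail quantitation but is recorded as a warning note.
#'
#' @param blanks a single blank (list of [SRMTrace]s, one per transition)
#'   or a list of such blanks
#' @param fit the [CalibrationFit] used for back-calculation
#' @param lod detection limit, pg/mg
#' @param window quantifier (and internal standard) integration window,
#'   `c(t_start, t_end)` seconds
#' @param noiseRegion peak-free region used for per-trace noise estimation
#' @param snrThreshold S/N above which a qualifier peak counts as a
#'   detectable interference (default 3)
#' @return list with `pass`, `perBlank` (data.frame with
#'   `apparent_pg_per_mg` and `pass`) and `warnings` (character)
#' @export
interferenceCheck <- function(blanks, fit, lod, window, noiseRegion,
                              snrThreshold = 3) {
  if (is(blanks[[1]], "SRMTrace")) blanks <- list(blanks)
  warnings <- character()
  rows <- lapply(seq_along(blanks), function(i) {
    traces <- blanks[[i]]
    roles <- vapply(traces, function(tr) tr@transition@role, character(1))
    if (!any(roles == "quantifier"))
      stop("blank ", i, ": quantifier trace missing")
    if (!any(roles == "internal_standard"))
      stop("blank ", i, ": internal standard trace missing")
    quant <- integratePeak(traces[[which(roles == "quantifier")[1]]], window)
    is_ <- integratePeak(traces[[which(roles == "internal_standard")[1]]],
                         window)
    if (!is_@area > 0)
      stop("blank ", i, ": internal standard peak absent")
    apparent <- backCalculate(fit, quant@area / is_@area)
    for (j in which(roles == "qualifier")) {
      tr <- traces[[j]]
      noise <- estimateNoiseRms(tr, noiseRegion, peakWindows = list(window))
      pk <- integratePeak(tr, window, noiseRms = max(noise, 1e-12))
      if (!is.na(pk@snr) && pk@snr > snrThreshold)
        warnings <<- c(warnings, sprintf(
          "blank %d: interference on qualifier %s (S/N %.1f)", i,
          transitionLabel(tr@transition), pk@snr))
    }
    data.frame(apparent_pg_per_mg = apparent, pass = apparent < lod)
  })
  perBlank <- do.call(rbind, rows)
  list(pass = all(perBlank$pass), perBlank = perBlank,
       warnings = unique(warnings))
}

#' Build per-level QC summaries from raw QC measurements
#'
#' For each nominal level, computes the intra-day summary on the first
#' day's replicates and the inter-day summary pooling all days.
#'
#' @param qc `data.frame` with columns `nominal_pg_per_mg`,
#'   `value_pg_per_mg` and `day`
#' @return `data.frame` with columns `nominal`, `scope`, `n`, `mean`, `sd`,
#'   `rsd_percent`, `bias_percent`
#' @export
qcSummary <- function(qc) {
  need <- c("nominal_pg_per_mg", "value_pg_per_mg", "day")
  if (!all(need %in% names(qc)))
    stop("QC table needs columns ", paste(need, collapse = ", "))
  rows <- list()
  for (nom in sort(unique(qc$nominal_pg_per_mg))) {
    sub <- qc[qc$nominal_pg_per_mg == nom, ]
    d1 <- sub[sub$day == min(sub$day), ]
    intra <- precisionTrueness(d1$value_pg_per_mg, nom, scope = "intra_day",
                               day = d1$day)
    inter <- precisionTrueness(sub$value_pg_per_mg, nom, scope = "inter_day",
                               day = sub$day)
    rows[[length(rows) + 1]] <- data.frame(
      nominal = nom, scope = c("intra_day", "inter_day"),
      n = c(intra$n, inter$n), mean = c(intra$mean, inter$mean),
      sd = c(intra$sd, inter$sd),
      rsd_percent = c(intra$rsd_percent, inter$rsd_percent),
      bias_percent = c(intra$bias_percent, inter$bias_percent))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the full validation report
#'
#' Combines the calibration fit, linearity verdicts, detection limits, LOQ,
#' QC precision/trueness and the interference check into one report. The
#' method passes overall when linearity is accepted (lack-of-fit and Mandel
#' both pass), the LOQ is defined, every QC level is within the RSD and
#' bias limits, and no blank shows quantifiable interference.
#'
#' @param fit a [CalibrationFit] (mandatory)
#' @param linearity a [LinearityVerdict] (mandatory)
#' @param lodResults list of [LodResult]s (by method tag)
#' @param loq the LOQ in pg/mg, or NA when undefined
#' @param qc per-level QC summary from [qcSummary()]
#' @param interference result of [interferenceCheck()], or NULL when not
#'   performed
#' @param limits list with elements `rsd` and `bias` (percent acceptance
#'   limits; default 15 and 20)
#' @return a [ValidationReport]
#' @export
assembleReport <- function(fit, linearity, lodResults = list(),
                           loq = NA_real_, qc = data.frame(),
                           interference = NULL,
                           limits = list(rsd = 15, bias = 20)) {
  if (missing(fit) || !is(fit, "CalibrationFit"))
    stop("missing mandatory component: calibration fit")
  if (missing(linearity) || !is(linearity, "LinearityVerdict"))
    stop("missing mandatory component: linearity verdict")
  loqDefined <- !is.na(loq)
  reasons <- character()
  if (!linearity@lofPass || !linearity@mandelPass)
    reasons <- c(reasons, "linearity rejected")
  if (!loqDefined) reasons <- c(reasons, "LOQ undefined")
  if (nrow(qc)) {
    bad <- qc$rsd_percent > limits$rsd | abs(qc$bias_percent) > limits$bias
    if (any(bad))
      reasons <- c(reasons, sprintf(
        "QC level %g (%s) outside limits (RSD %.1f%%, bias %.1f%%)",
        qc$nominal[bad], qc$scope[bad], qc$rsd_percent[bad],
        qc$bias_percent[bad]))
  }
  if (!is.null(interference) && !interference$pass)
    reasons <- c(reasons, "interference above LOD in blank hair")
  new("ValidationReport", fit = fit, linearity = linearity,
      lodResults = lodResults, loq = as.numeric(loq),
      loqDefined = loqDefined, qc = qc,
      interference = interference %||% list(), limits = limits,
      overallPass = length(reasons) == 0, reasons = reasons)
}

#' Serialize a validation report to JSON
#'
#' RSD values are printed as integers and bias to one decimal (half-up),
#' alongside the exact unrounded values.
#'
#' @param report a [ValidationReport]
#' @param path output file
#' @return the report list, invisibly
#' @export
writeValidationReport <- function(report, path) {
  lodList <- lapply(report@lodResults, function(l) list(
    method = l@method, lod_pg_per_mg = l@lod,
    decision_limit_pg_per_mg = l@decisionLimit, alpha = l@alpha,
    beta = l@beta, determined = l@determined))
  qc <- report@qc
  if (nrow(qc)) {
    qc$rsd_printed <- roundHalfUp(qc$rsd_percent)
    qc$bias_printed <- roundHalfUp(abs(qc$bias_percent), 1)
  }
  out <- list(
    calibration = list(
      slope = report@fit@slope, intercept = report@fit@intercept,
      residual_sd = report@fit@residualSd, n = report@fit@n,
      r_squared = report@fit@rSquared,
      range_pg_per_mg = report@fit@range),
    linearity = list(
      alpha = report@linearity@alpha,
      fisher = list(F = report@linearity@fisherF,
                    pass = report@linearity@fisherPass),
      lack_of_fit = list(F = report@linearity@lofF,
                         df = report@linearity@lofDf,
                         pass = report@linearity@lofPass),
      mandel = list(F = report@linearity@mandelF,
                    df = report@linearity@mandelDf,
                    pass = report@linearity@mandelPass)),
    lod = lodList,
    loq_pg_per_mg = if (report@loqDefined) report@loq else NULL,
    qc = qc,
    interference = if (length(report@interference))
      list(pass = report@interference$pass,
           warnings = report@interference$warnings) else NULL,
    limits = report@limits,
    overall_pass = report@overallPass,
    reasons = report@reasons)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "rows")
  invisible(out)
}
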