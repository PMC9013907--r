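## Pipeline configuration and runnable entry points tying the stages
## together. A thin command-line wrapper over these functions ships in
## inst/cli/hairetg.R.

#' Pipeline configuration
#'
#' Central defaults quoted throughout the method: linearity tests at alpha
#' 0.05, Fisher homoscedasticity at 0.01, Hubaux-Vos alpha = beta = 0.05,
#' ion-ratio tolerance +/- 20\%, QC limits 15\% RSD / 20\% bias, SoHT
#' cut-off 30 pg/mg, LOD 4 and LOQ 6 pg/mg, working ranges 6-60 and 60-300
#' pg/mg, 50 mg reference sample mass, factorial significance threshold
#' 19.71 pg/mg.
#'
#' @param fisherAlpha,linearityAlpha,hvAlpha,hvBeta significance/error
#'   rates, each in (0, 1)
#' @param ionRatioTolerance relative ion-ratio tolerance (> 0)
#' @param rsdLimit,biasLimit QC acceptance limits in percent
#' @param cutoff SoHT decision threshold, pg/mg
#' @param lod,loq method detection/quantification limits, pg/mg
#' @param lowRange,highRange calibration working ranges, pg/mg
#' @param referenceMass calibrator hair mass, mg
#' @param doeThreshold fixed significance threshold for factorial effects,
#'   pg/mg
#' @param doeMaxOrder highest interaction order reported by [runDoe()]
#' @param seed optional integer seed for simulation commands
#' @return a validated configuration list of class `PipelineConfig`
#' @export
pipelineConfig <- function(fisherAlpha = 0.01, linearityAlpha = 0.05,
                           hvAlpha = 0.05, hvBeta = 0.05,
                           ionRatioTolerance = 0.2, rsdLimit = 15,
                           biasLimit = 20, cutoff = 30, lod = 4, loq = 6,
                           lowRange = c(6, 60), highRange = c(60, 300),
                           referenceMass = 50, doeThreshold = 19.71,
                           doeMaxOrder = 2, seed = NULL) {
  cfg <- list(fisherAlpha = fisherAlpha, linearityAlpha = linearityAlpha,
              hvAlpha = hvAlpha, hvBeta = hvBeta,
              ionRatioTolerance = ionRatioTolerance, rsdLimit = rsdLimit,
              biasLimit = biasLimit, cutoff = cutoff, lod = lod, loq = loq,
              lowRange = lowRange, highRange = highRange,
              referenceMass = referenceMass, doeThreshold = doeThreshold,
              doeMaxOrder = doeMaxOrder, seed = seed)
  rates <- c(fisherAlpha, linearityAlpha, hvAlpha, hvBeta)
  if (any(rates <= 0 | rates >= 1))
    stop("all significance/error rates must lie in (0, 1)")
  if (!ionRatioTolerance > 0) stop("ionRatioTolerance must be > 0")
  if (!cutoff > 0) stop("cutoff must be > 0")
  if (!(lod > 0 && lod <= loq)) stop("need 0 < lod <= loq")
  if (!(rsdLimit > 0 && biasLimit > 0)) stop("QC limits must be > 0")
  class(cfg) <- "PipelineConfig"
  cfg
}

.specFromList <- function(sp, seed = NULL) {
  type <- sp$type %||% stop("simulation spec needs a 'type' field")
  if (!is.null(seed)) sp$seed <- seed
  switch(type,
    trace = TraceSpec(
      transitions = sp$transitions,
      duration = sp$duration %||% 60,
      samplingInterval = sp$sampling_interval %||% 0.1,
      peaks = if (!is.null(sp$peaks)) as.data.frame(sp$peaks)
              else data.frame(),
      baselineLevel = sp$baseline_level %||% 0,
      noiseSd = sp$noise_sd %||% 0,
      interference = if (!is.null(sp$interference))
        as.data.frame(sp$interference) else NULL,
      seed = sp$seed %||% 1),
    calibration = CalibrationSimSpec(
      levels = sp$levels %||% c(6, 10, 20, 30, 60),
      replicates = sp$replicates_per_level %||% 3,
      slope = sp$slope %||% 0.01, intercept = sp$intercept %||% 0,
      noiseModel = sp$noise_model %||% "constant_sd",
      noiseParam = sp$noise_param %||% 0.01,
      curvature = sp$curvature %||% 0, seed = sp$seed %||% 1),
    factorial = FactorialSimSpec(
      k = sp$k %||% 3,
      trueEffects = unlist(sp$true_effects %||%
        list(a = 3.55, b = 34.95, c = 66.95, ab = 6.5, ac = -11.7,
             bc = -36)),
      grandMean = sp$grand_mean %||% 147.3,
      replicateBlocks = sp$replicate_blocks %||% 3,
      noiseSd = sp$noise_sd %||% 8, seed = sp$seed %||% 1),
    cohort = CohortSimSpec(
      categorySizes = unlist(sp$category_sizes %||%
        list(Teetotal = 6, Light = 6, Social = 4, Moderate = 6, Heavy = 3)),
      lognormalParams = if (!is.null(sp$lognormal_params))
        as.data.frame(sp$lognormal_params)
      else eval(formals(CohortSimSpec)$lognormalParams),
      lod = sp$lod %||% 4, loq = sp$loq %||% 6, seed = sp$seed %||% 1),
    stop("unknown simulation type '", type, "'")
  )
}

#' Generate simulated input files
#'
#' Reads a JSON simulation spec (field `type` one of `trace`,
#' `calibration`, `factorial`, `cohort`; remaining fields mirror the
#' corresponding spec constructor), writes the simulated table(s) as CSV
#' into `outDir` together with a `manifest.json` recording the seed and the
#' spec file hash. Identical spec and seed give byte-identical outputs.
#'
#' @param specFile JSON spec file
#' @param outDir output directory (created if needed)
#' @param seed optional seed override
#' @return paths of the written files, invisibly
#' @export
runSimulate <- function(specFile, outDir, seed = NULL) {
  sp <- jsonlite::read_json(specFile, simplifyVector = TRUE)
  spec <- .specFromList(sp, seed = seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  type <- sp$type
  dataPath <- file.path(outDir, paste0(type, ".csv"))
  if (type == "trace") {
    traces <- simulateTraces(spec)
    long <- do.call(rbind, lapply(names(traces), function(id)
      data.frame(time_s = traces[[id]]@times, transition_id = id,
                 intensity = traces[[id]]@intensities)))
    write.csv(long, dataPath, row.names = FALSE)
  } else {
    df <- switch(type,
                 calibration = simulateCalibration(spec),
                 factorial = simulateFactorial(spec),
                 cohort = simulateCohort(spec))
    write.csv(df, dataPath, row.names = FALSE)
  }
  manifest <- list(type = type, seed = spec@seed,
                   spec_md5 = unname(tools::md5sum(specFile)),
                   files = basename(dataPath))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(dataPath, manifestPath))
}

#' Run the full validation pipeline
#'
#' Pipeline order: homoscedasticity check, unweighted fit, linearity tests,
#' Hubaux-Vos LOD, LOQ, per-level precision/trueness, report assembly. The
#' configured LOQ (`config$loq`) is used when provided; otherwise the LOQ
#' is determined from the intra-day QC summaries.
#'
#' @param calibrationCsv calibration CSV (see [readCalibrationTable()])
#' @param qcCsv QC CSV (see [readQcTable()])
#' @param config a [pipelineConfig()]
#' @param out optional path for the JSON report
#' @return the [ValidationReport], invisibly
#' @export
runValidate <- function(calibrationCsv, qcCsv, config = pipelineConfig(),
                        out = NULL) {
  cal <- readCalibrationTable(calibrationCsv)
  qcRaw <- readQcTable(qcCsv)
  fit <- fitCalibration(cal)
  fit@range <- as.numeric(config$lowRange)
  lin <- linearityVerdict(cal, alpha = config$linearityAlpha,
                          fisherAlpha = config$fisherAlpha, fit = fit)
  lodHv <- lodHubauxVos(fit, alpha = config$hvAlpha, beta = config$hvBeta)
  qc <- qcSummary(qcRaw)
  loq <- if (!is.null(config$loq)) config$loq else {
    intra <- qc[qc$scope == "intra_day", ]
    determineLoq(data.frame(level = intra$nominal,
                            cv_percent = intra$rsd_percent,
                            bias_percent = intra$bias_percent))$loq
  }
  report <- assembleReport(fit, lin, lodResults = list(hubaux_vos = lodHv),
                           loq = loq %||% NA_real_, qc = qc,
                           limits = list(rsd = config$rsdLimit,
                                         bias = config$biasLimit))
  if (!is.null(out)) writeValidationReport(report, out)
  invisible(report)
}

#' Run the factorial-effects pipeline
#'
#' @param doeCsv DoE CSV (see [readDoeTable()])
#' @param config a [pipelineConfig()]; `doeThreshold` sets the fixed
#'   significance threshold, `doeMaxOrder` the highest interaction order
#' @param out optional path; `.json` or `.csv` by extension
#' @return `data.frame` of flagged effects, invisibly
#' @export
runDoe <- function(doeCsv, config = pipelineConfig(), out = NULL) {
  tab <- readDoeTable(doeCsv)
  eff <- estimateEffects(tab, maxOrder = config$doeMaxOrder)
  eff <- flagSignificance(eff, mode = "fixed_threshold",
                          threshold = config$doeThreshold)
  if (!is.null(out)) {
    if (grepl("\\.json$", out))
      jsonlite::write_json(eff, out, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    else write.csv(eff, out, row.names = FALSE)
  }
  invisible(eff)
}

#' Run the cohort-interpretation pipeline
#'
#' @param cohortCsv cohort CSV (see [readCohortTable()])
#' @param config a [pipelineConfig()]; `cutoff` sets the decision threshold
#' @param out optional path for the JSON summary
#' @return list with `summaries` (per-class), `classification` (per
#'   subject) and `anomalies`, invisibly
#' @export
runCohort <- function(cohortCsv, config = pipelineConfig(), out = NULL) {
  records <- readCohortTable(cohortCsv)
  summaries <- summarizeByClass(records, cutoff = config$cutoff)
  records$cutoff_verdict <- classifyVsCutoff(records$etg_pg_per_mg,
                                             records$etg_status,
                                             cutoff = config$cutoff)
  res <- list(summaries = summaries,
              classification = records,
              anomalies = flagAnomalies(records))
  if (!is.null(out))
    jsonlite::write_json(
      list(cutoff_pg_per_mg = config$cutoff, summaries = summaries,
           anomalies = res$anomalies), out,
      auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null",
      factor = "string")
  invisible(res)
}
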