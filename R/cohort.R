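## Censoring-aware cohort interpretation against the SoHT cut-off.

#' Ordered drinking classes
#'
#' Declared-consumption categories in increasing order of weekly intake:
#' Teetotal (0 units/week) < Light (>5) < Social (>10) < Moderate (>15) <
#' Heavy (>25), one unit = 12 g pure ethanol.
#'
#' @return character vector of class labels, lowest first
#' @export
drinkingClasses <- function() {
  c("Teetotal", "Light", "Social", "Moderate", "Heavy")
}

#' Censor a concentration at the LOD and LOQ
#'
#' Values below the LOD (including negative back-calculations) are reported
#' as `below_lod`, values in [LOD, LOQ) as `below_loq`, and values at or
#' above the LOQ as `quantified`. Censored values are never imputed.
#'
#' @param value concentration(s) in pg/mg; may be negative
#' @param lod,loq censoring limits, `0 < lod <= loq`
#' @return `data.frame` with columns `etg_pg_per_mg` (NA when censored) and
#'   `etg_status` (factor: `below_lod`, `below_loq`, `quantified`)
#' @examples
#' censorConcentration(c(3, 5, 14.9), lod = 4, loq = 6)
#' @export
censorConcentration <- function(value, lod, loq) {
  if (!(lod > 0 && lod <= loq))
    stop("configuration error: need 0 < lod <= loq")
  status <- ifelse(value < lod, "below_lod",
                   ifelse(value < loq, "below_loq", "quantified"))
  data.frame(
    etg_pg_per_mg = ifelse(status == "quantified", value, NA_real_),
    etg_status = factor(status,
                        levels = c("below_lod", "below_loq", "quantified")))
}

#' Classify a result against the chronic-excessive-drinking cut-off
#'
#' A quantified concentration at or above the cut-off (30 pg/mg per the
#' Society of Hair Testing) indicates chronic excessive drinking; censored
#' or lower results are below the cut-off. Abstinence assessment requires a
#' method LOQ of 5 pg/mg or lower; with a higher LOQ the result is
#' `not_assessable_abstinence` regardless of the measurement.
#'
#' @param etg quantified concentration in pg/mg, or NA when censored
#' @param status `"quantified"`, `"below_loq"` or `"below_lod"`
#' @param cutoff decision threshold in pg/mg (> 0), default 30
#' @param purpose `"excessive_drinking"` or `"abstinence"`
#' @param loq the method LOQ, required for abstinence assessment
#' @return one of `"exceeds_cutoff"`, `"below_cutoff"`,
#'   `"not_assessable_abstinence"` (vectorized over `etg`/`status`)
#' @examples
#' classifyVsCutoff(127.9, "quantified")
#' classifyVsCutoff(NA, "below_lod", purpose = "abstinence", loq = 6)
#' @export
classifyVsCutoff <- function(etg, status, cutoff = 30,
                             purpose = c("excessive_drinking", "abstinence"),
                             loq = NULL) {
  purpose <- match.arg(purpose)
  if (!cutoff > 0) stop("cutoff must be > 0")
  if (purpose == "abstinence") {
    if (is.null(loq)) stop("abstinence assessment requires the method LOQ")
    if (loq > 5)
      return(rep("not_assessable_abstinence", length(status)))
  }
  ifelse(status == "quantified" & !is.na(etg) & etg >= cutoff,
         "exceeds_cutoff", "below_cutoff")
}

#' Summarize cohort results by declared drinking class
#'
#' Per class: subject count, number with a quantified result, order
#' statistics (min/median/max) of the quantified values only — censored
#' records are counted but never imputed — and the number of quantified
#' results at or above the cut-off.
#'
#' @param records cohort `data.frame` with columns `drinking_class`,
#'   `etg_pg_per_mg` and `etg_status` (as from [simulateCohort()] or
#'   `loadFixture("cohort_table5")`)
#' @param cutoff decision threshold in pg/mg, default 30
#' @return `data.frame`, one row per class present
#' @examples
#' summarizeByClass(loadFixture("cohort_table5"))
#' @export
summarizeByClass <- function(records, cutoff = 30) {
  if (!nrow(records)) stop("empty cohort")
  if (!cutoff > 0) stop("cutoff must be > 0")
  cls <- intersect(drinkingClasses(), unique(as.character(records$drinking_class)))
  rows <- lapply(cls, function(cl) {
    sub <- records[records$drinking_class == cl, ]
    q <- sub$etg_pg_per_mg[sub$etg_status == "quantified"]
    q <- q[!is.na(q)]
    data.frame(
      class = cl, n = nrow(sub), n_quantified = length(q),
      min = if (length(q)) min(q) else NA_real_,
      median = if (length(q)) median(q) else NA_real_,
      max = if (length(q)) max(q) else NA_real_,
      n_above_cutoff = sum(q >= cutoff))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' List declared-vs-measured discordances
#'
#' Flags subjects whose declared class is Moderate or higher but whose
#' result is censored (below LOQ or LOD) — reported as anomalies for
#' review, with no numeric adjustment.
#'
#' @param records cohort `data.frame` (see [summarizeByClass()])
#' @return subset of `records` with the discordant subjects
#' @export
flagAnomalies <- function(records) {
  disc <- as.character(records$drinking_class) %in% c("Moderate", "Heavy") &
    records$etg_status != "quantified"
  records[disc, , drop = FALSE]
}

#' Box-and-whisker plot of cohort results by class
#'
#' Quantified values only, with the cut-off drawn as a dashed line.
#'
#' @param records cohort `data.frame`
#' @param cutoff decision threshold in pg/mg
#' @param ... passed to [graphics::boxplot()]
#' @return invisibly, the list returned by `boxplot`
#' @export
plotCohort <- function(records, cutoff = 30, ...) {
  q <- records[records$etg_status == "quantified", ]
  bp <- graphics::boxplot(
    etg_pg_per_mg ~ factor(as.character(drinking_class),
                           levels = drinkingClasses()),
    data = q, ylab = "EtG (pg/mg)", xlab = "Declared drinking class", ...)
  graphics::abline(h = cutoff, lty = 2)
  invisible(bp)
}
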