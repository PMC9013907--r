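## Strict CSV readers for the pipeline. Dialect is fixed: comma separator,
## dot decimal, UTF-8, header row required. European decimal commas are
## rejected with row/column coordinates, never silently parsed.

.parseNumericStrict <- function(x, file, column, allowNa = FALSE) {
  x <- trimws(as.character(x))
  bad <- grepl(",", x, fixed = TRUE)
  if (any(bad))
    stop(sprintf(
      "%s: column '%s', row(s) %s: decimal commas are not accepted (use '.')",
      file, column, paste(which(bad), collapse = ", ")))
  out <- suppressWarnings(as.numeric(x))
  miss <- is.na(out) & !is.na(x) & !(x %in% c("", "NA"))
  if (any(miss))
    stop(sprintf("%s: column '%s', row(s) %s: not a number",
                 file, column, paste(which(miss), collapse = ", ")))
  if (!allowNa && any(is.na(out)))
    stop(sprintf("%s: column '%s' contains missing values", file, column))
  out
}

.requireColumns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s) %s", file,
                 paste(miss, collapse = ", ")))
  invisible(df)
}

.readCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  if (!nrow(df)) stop(path, ": no data rows")
  df
}

#' Read a calibration CSV
#'
#' Expected columns: `nominal_pg_per_mg`, `response_ratio`, optionally
#' `replicate` and `batch`.
#'
#' @param path CSV file
#' @return `data.frame` ready for [fitCalibration()]
#' @export
readCalibrationTable <- function(path) {
  df <- .readCsv(path)
  .requireColumns(df, c("nominal_pg_per_mg", "response_ratio"), path)
  df$nominal_pg_per_mg <- .parseNumericStrict(df$nominal_pg_per_mg, path,
                                              "nominal_pg_per_mg")
  df$response_ratio <- .parseNumericStrict(df$response_ratio, path,
                                           "response_ratio")
  if ("replicate" %in% names(df))
    df$replicate <- as.integer(.parseNumericStrict(df$replicate, path,
                                                   "replicate"))
  df
}

#' Read a QC measurement CSV
#'
#' Expected columns: `nominal_pg_per_mg`, `value_pg_per_mg`, `day`,
#' optionally `operator`.
#'
#' @param path CSV file
#' @return `data.frame` ready for [qcSummary()]
#' @export
readQcTable <- function(path) {
  df <- .readCsv(path)
  .requireColumns(df, c("nominal_pg_per_mg", "value_pg_per_mg", "day"), path)
  df$nominal_pg_per_mg <- .parseNumericStrict(df$nominal_pg_per_mg, path,
                                              "nominal_pg_per_mg")
  df$value_pg_per_mg <- .parseNumericStrict(df$value_pg_per_mg, path,
                                            "value_pg_per_mg")
  df
}

#' Read a factorial-design CSV
#'
#' Expected columns: `run_label`, coded-level columns (one per factor
#' letter, values -1/+1), `response_pg_per_mg`, optionally `block`.
#'
#' @param path CSV file
#' @return `data.frame` ready for [estimateEffects()]
#' @export
readDoeTable <- function(path) {
  df <- .readCsv(path)
  .requireColumns(df, c("run_label", "response_pg_per_mg"), path)
  for (col in intersect(c(letters[1:8], "block"), names(df)))
    df[[col]] <- as.integer(.parseNumericStrict(df[[col]], path, col))
  df$response_pg_per_mg <- .parseNumericStrict(df$response_pg_per_mg, path,
                                               "response_pg_per_mg")
  df
}

#' Read a cohort CSV
#'
#' Expected columns: `drinking_class` and `etg` (a number, `<LOD` or
#' `<LOQ`); other subject columns are carried through. Alternatively the
#' already-parsed pair `etg_pg_per_mg`/`etg_status` is accepted.
#'
#' @param path CSV file
#' @return `data.frame` ready for [summarizeByClass()]
#' @export
readCohortTable <- function(path) {
  df <- .readCsv(path)
  .requireColumns(df, "drinking_class", path)
  unknown <- setdiff(unique(df$drinking_class), drinkingClasses())
  if (length(unknown))
    stop(sprintf("%s: unknown drinking class label(s) %s", path,
                 paste(unknown, collapse = ", ")))
  if (!"etg_status" %in% names(df)) {
    .requireColumns(df, "etg", path)
    st <- rep("quantified", nrow(df))
    st[df$etg == "<LOD"] <- "below_lod"
    st[df$etg == "<LOQ"] <- "below_loq"
    df$etg_status <- factor(st, levels = c("below_lod", "below_loq",
                                           "quantified"))
    num <- df$etg
    num[df$etg_status != "quantified"] <- NA
    df$etg_pg_per_mg <- .parseNumericStrict(num, path, "etg", allowNa = TRUE)
  } else {
    df$etg_pg_per_mg <- .parseNumericStrict(df$etg_pg_per_mg, path,
                                            "etg_pg_per_mg", allowNa = TRUE)
  }
  df$drinking_class <- factor(df$drinking_class, levels = drinkingClasses(),
                              ordered = TRUE)
  df
}
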