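## Packaged data tables from the published validation study, shipped as
## plain CSV under extdata and normalized on load.

.fixtureNames <- c("doe_table3", "validation_table4", "cohort_table5",
                   "srm_method")

#' Load a packaged data table
#'
#' Available fixtures:
#' \describe{
#'   \item{`doe_table3`}{the eight-run 2^3 factorial pretreatment
#'     experiment on one heavy-drinker donor, remapped to standard Yates
#'     run order, with the published factor values and significance calls
#'     retained in columns `factor_value` and `significant`; the published
#'     significance threshold (19.71 pg/mg) is attached as attribute
#'     `significanceThreshold`.}
#'   \item{`validation_table4`}{per-level intra-/inter-day precision and
#'     trueness summaries (mean, SD, RSD\%, bias\%) at 20, 30 and 60 pg/mg
#'     plus the LOQ-level (6 pg/mg) intra-day summary.}
#'   \item{`cohort_table5`}{the 25-subject cohort with declared drinking
#'     class and possibly censored EtG result; parsed into
#'     `etg_pg_per_mg`/`etg_status` with `drinking_class` as an ordered
#'     factor.}
#'   \item{`srm_method`}{the four-transition SRM acquisition scheme (use
#'     [srmMethodFromTable()] to build an [SRMMethod]).}
#' }
#'
#' @param name fixture identifier, one of the above
#' @return a `data.frame`
#' @examples
#' loadFixture("doe_table3")
#' @export
loadFixture <- function(name) {
  if (!name %in% .fixtureNames)
    stop("unknown fixture '", name, "'; available: ",
         paste(.fixtureNames, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".csv"), package = "hairEtG",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  switch(name,
    doe_table3 = .loadDoeTable3(df),
    cohort_table5 = .loadCohortTable5(df),
    validation_table4 = df,
    srm_method = df
  )
}

.loadDoeTable3 <- function(df) {
  yates <- c("0", "a", "b", "ab", "c", "ac", "bc", "abc")
  stopifnot(setequal(df$run_label, yates))
  df <- df[match(yates, df$run_label), ]
  out <- cbind(data.frame(block = 1L), df)
  rownames(out) <- NULL
  # the printed threshold "(19,71)" uses a European decimal comma
  attr(out, "significanceThreshold") <- 19.71
  out
}

.loadCohortTable5 <- function(df) {
  st <- rep("quantified", nrow(df))
  st[df$etg == "<LOD"] <- "below_lod"
  st[df$etg == "<LOQ"] <- "below_loq"
  df$etg_status <- factor(st,
                          levels = c("below_lod", "below_loq", "quantified"))
  df$etg_pg_per_mg <- ifelse(df$etg_status == "quantified",
                             suppressWarnings(as.numeric(df$etg)), NA_real_)
  df$drinking_class <- factor(df$drinking_class, levels = drinkingClasses(),
                              ordered = TRUE)
  df$cosmetic_treatment <- df$cosmetic_treatment == "Yes"
  # lengths reported as a range ("4-5") are taken at the midpoint
  df$hair_length_num <- vapply(strsplit(df$hair_length_cm, "-"),
                               function(p) mean(as.numeric(p)), numeric(1))
  df
}

#' Build an SRMMethod from a transition table
#'
#' @param df `data.frame` with columns `precursor_mz`, `product_mz`,
#'   `collision_energy_v` and `role`, as returned by
#'   `loadFixture("srm_method")`
#' @return an [SRMMethod]
#' @examples
#' srmMethodFromTable(loadFixture("srm_method"))
#' @export
srmMethodFromTable <- function(df) {
  tr <- lapply(seq_len(nrow(df)), function(i)
    Transition(df$precursor_mz[i], df$product_mz[i],
               df$collision_energy_v[i], df$role[i]))
  do.call(SRMMethod, tr)
}
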