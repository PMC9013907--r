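## 2^k full-factorial analysis of the pretreatment experiment: effect
## estimation by contrasts, significance flagging, and pairwise
## extraction-yield deficits.

.doeFactors <- function(table) {
  f <- intersect(letters, names(table))
  f[order(match(f, letters))]
}

.checkDoeTable <- function(table) {
  if (!"response_pg_per_mg" %in% names(table))
    stop("DoE table needs a response_pg_per_mg column")
  f <- .doeFactors(table)
  if (length(f) < 2) stop("DoE table needs >= 2 coded factor columns")
  k <- length(f)
  if (!"block" %in% names(table)) table$block <- 1L
  expected <- yatesDesign(k)
  for (b in unique(table$block)) {
    tb <- table[table$block == b, ]
    key <- apply(tb[, f, drop = FALSE], 1, paste, collapse = ",")
    ekey <- apply(expected[, f, drop = FALSE], 1, paste, collapse = ",")
    missing <- setdiff(ekey, key)
    if (length(missing) || nrow(tb) != 2^k) {
      miss <- expected$run_label[match(missing, ekey)]
      stop("incomplete design in block ", b, ": missing run(s) ",
           paste(miss, collapse = ", "))
    }
  }
  table
}

#' Estimate factorial effects by contrasts
#'
#' The effect of a factor subset S is the contrast
#' \deqn{\mathrm{effect}(S) = \frac{1}{2^{k-1}} \sum_{runs} y \prod_{f \in S}
#'   x_f}
#' with coded levels \eqn{x_f \in \{-1, +1\}} — the mean response at the
#' high setting minus the mean at the low setting (for k = 3, contrast/4).
#' Replicate blocks are averaged run-wise before the contrast is taken.
#'
#' @param table `data.frame` with columns `run_label`, one coded-level
#'   column per factor letter, `response_pg_per_mg`, and optionally `block`;
#'   each block must contain each level combination exactly once
#' @param maxOrder highest interaction order to report (default: all, i.e.
#'   `k`)
#' @return `data.frame` with columns `label` and `value` (pg/mg), ordered
#'   by interaction order
#' @examples
#' estimateEffects(loadFixture("doe_table3"))
#' @export
estimateEffects <- function(table, maxOrder = NULL) {
  table <- .checkDoeTable(table)
  f <- .doeFactors(table)
  k <- length(f)
  maxOrder <- maxOrder %||% k
  key <- apply(table[, f, drop = FALSE], 1, paste, collapse = ",")
  ybar <- tapply(table$response_pg_per_mg, key, mean)
  des <- yatesDesign(k)
  dkey <- apply(des[, f, drop = FALSE], 1, paste, collapse = ",")
  y <- as.numeric(ybar[dkey])
  labs <- effectLabels(k, maxOrder)
  vals <- vapply(labs, function(lab) {
    sgn <- apply(des[, strsplit(lab, "")[[1]], drop = FALSE], 1, prod)
    sum(y * sgn) / 2^(k - 1)
  }, numeric(1))
  data.frame(label = labs, value = unname(vals), stringsAsFactors = FALSE)
}

#' Flag significant factorial effects
#'
#' Three flagging modes are supported:
#' \describe{
#'   \item{`fixed_threshold`}{an effect is significant when its absolute
#'     value exceeds a stated threshold in pg/mg (default 19.71, the
#'     published decision value for the pretreatment experiment).}
#'   \item{`replicate_t`}{per-block effects are computed from `table`
#'     (>= 2 blocks) and each effect is tested with a one-sample t
#'     statistic against zero at level `alpha`.}
#'   \item{`lenth`}{Lenth's pseudo-standard-error margin for unreplicated
#'     designs (>= 7 effect estimates).}
#' }
#'
#' @param effects `data.frame` from [estimateEffects()]
#' @param mode one of `"fixed_threshold"`, `"replicate_t"`, `"lenth"`
#' @param threshold pg/mg threshold for `fixed_threshold`
#' @param alpha significance level for `replicate_t` and `lenth`
#' @param table the DoE table, required for `replicate_t`
#' @return `effects` with added columns `significant` and `threshold` (the
#'   pg/mg margin actually applied to each effect)
#' @examples
#' eff <- estimateEffects(loadFixture("doe_table3"), maxOrder = 2)
#' flagSignificance(eff)
#' @export
flagSignificance <- function(effects,
                             mode = c("fixed_threshold", "replicate_t",
                                      "lenth"),
                             threshold = 19.71, alpha = 0.05, table = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_threshold") {
    if (is.null(threshold) || is.na(threshold))
      stop("fixed_threshold mode requires a threshold")
    effects$significant <- abs(effects$value) > threshold
    effects$threshold <- threshold
  } else if (mode == "replicate_t") {
    if (is.null(table)) stop("replicate_t mode requires the DoE table")
    table <- .checkDoeTable(table)
    blocks <- unique(table$block)
    if (length(blocks) < 2)
      stop("replicate_t mode requires >= 2 replicate blocks")
    perBlock <- vapply(blocks, function(b) {
      e <- estimateEffects(table[table$block == b, ])
      e$value[match(effects$label, e$label)]
    }, numeric(nrow(effects)))
    perBlock <- matrix(perBlock, nrow = nrow(effects))
    m <- rowMeans(perBlock)
    se <- apply(perBlock, 1, sd) / sqrt(length(blocks))
    tc <- qt(1 - alpha / 2, length(blocks) - 1)
    effects$significant <- abs(m) > tc * se
    effects$threshold <- tc * se
  } else {
    if (nrow(effects) < 7)
      stop("lenth mode requires >= 7 effect estimates")
    v <- abs(effects$value)
    s0 <- 1.5 * median(v)
    pse <- 1.5 * median(v[v < 2.5 * s0])
    d <- nrow(effects) / 3
    me <- qt(1 - alpha / 2, d) * pse
    effects$significant <- v > me
    effects$threshold <- me
  }
  attr(effects, "test_meta") <- list(mode = mode, alpha = alpha)
  effects
}

#' Pairwise extraction-yield deficits
#'
#' For each (numerator, denominator) pair of run labels, the percent
#' deficit `100 * (1 - y[num] / y[den])`, rounded half-up to integer
#' percent. Run labels may also be given as `"x+y"` to average runs before
#' taking the ratio (e.g. `"0+a"`).
#'
#' @param table DoE table (block-averaged before use)
#' @param pairs list of `c(numerator, denominator)` label pairs
#' @return integer percent deficits, one per pair
#' @examples
#' yieldDeficit(loadFixture("doe_table3"),
#'              list(c("b", "c"), c("ab", "ac")))
#' @export
yieldDeficit <- function(table, pairs) {
  table <- .checkDoeTable(table)
  ybar <- tapply(table$response_pg_per_mg, table$run_label, mean)
  value <- function(spec) {
    labs <- strsplit(spec, "+", fixed = TRUE)[[1]]
    if (!all(labs %in% names(ybar)))
      stop("unknown run label(s): ",
           paste(setdiff(labs, names(ybar)), collapse = ", "))
    mean(ybar[labs])
  }
  vapply(pairs, function(p) {
    num <- value(p[1])
    den <- value(p[2])
    if (den <= 0) stop("denominator response must be > 0 for pair ",
                       paste(p, collapse = " vs "))
    roundHalfUp(100 * (1 - num / den))
  }, numeric(1))
}
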