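# shared internal helpers

# round half away from zero (report convention; base round() is banker's)
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream
withSeed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

windowsOverlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative standard deviation in percent
#'
#' @param mean mean measured value
#' @param sd sample standard deviation (n - 1 denominator)
#' @return `100 * sd / mean`, unrounded
#' @export
rsdPercent <- function(mean, sd) 100 * sd / mean

#' Signed relative bias in percent
#'
#' @param mean mean measured value
#' @param nominal nominal (spiked) value
#' @return `100 * (mean - nominal) / nominal`, unrounded
#' @export
biasPercent <- function(mean, nominal) 100 * (mean - nominal) / nominal
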