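test_that("precision and trueness use sample statistics and signed bias", {
  v <- c(19.9, 17.2, 22.1)
  res <- precisionTrueness(v, nominal = 20, scope = "intra_day")
  expect_equal(res$mean, mean(v))
  expect_equal(res$sd, sd(v))
  expect_equal(res$rsd_percent, 100 * sd(v) / mean(v))
  expect_equal(res$bias_percent, 100 * (mean(v) - 20) / 20)

  same <- rep(30, 5)
  res <- precisionTrueness(same, 30, scope = "intra_day")
  expect_equal(res$rsd_percent, 0)
  expect_equal(res$bias_percent, 0)

  # mean 5.66 at nominal 6 rounds to a 6% bias magnitude
  expect_equal(round(abs(biasPercent(5.66, 6))), 6)
})

test_that("scope and grouping are enforced", {
  expect_error(precisionTrueness(c(1, 2, 3), 2, scope = "intra_day",
                                 day = c(1, 1, 2)), "single day")
  expect_error(precisionTrueness(c(1, 2), 2, scope = "intra_day"), ">= 3")
  expect_error(precisionTrueness(c(1, 2, 3), 2, scope = "inter_day",
                                 day = c(1, 1, 1)), "2 distinct days")
  expect_error(precisionTrueness(c(1, 2, 3), 2, scope = "inter_day"),
               "day identifiers")
})

test_that("reported RSD converges to the generating CV on synthetic QC data", {
  set.seed(14)
  v <- 30 * (1 + rnorm(1000, 0, 0.10))
  res <- precisionTrueness(v, 30, scope = "inter_day",
                           day = rep(1:10, each = 100))
  expect_lt(abs(res$rsd_percent - 10), 1)
  expect_lt(abs(res$bias_percent), 1)
})

test_that("QC summaries are internally consistent", {
  set.seed(15)
  qc <- data.frame(
    nominal_pg_per_mg = rep(c(20, 30, 60), each = 9),
    value_pg_per_mg = rep(c(20, 30, 60), each = 9) *
      (1 + rnorm(27, 0, 0.08)),
    day = rep(rep(1:3, each = 3), times = 3))
  s <- qcSummary(qc)
  expect_equal(s$rsd_percent, 100 * s$sd / s$mean)
  expect_equal(s$bias_percent, 100 * (s$mean - s$nominal) / s$nominal)
  expect_equal(nrow(s), 6)
  expect_equal(s$n[s$scope == "inter_day"], rep(9L, 3))
})

test_that("blank interference check back-calculates against the LOD", {
  x <- c(6, 10, 20, 30, 60)
  fit <- fitCalibration(calTable(x, 0.01 * x))
  mkBlank <- function(quantHeight = 0, qualHeight = 0) {
    m <- etgSrmMethod()
    list(
      gaussTrace(rt = 250, height = quantHeight, sigma = 3, duration = 300,
                 dt = 0.2, transition = quantifier(m)),
      gaussTrace(rt = 250, height = 2000, sigma = 3, duration = 300,
                 dt = 0.2, transition = internalStandard(m)),
      gaussTrace(rt = 250, height = qualHeight, sigma = 3, duration = 300,
                 dt = 0.2, transition = qualifiers(m)[[1]])
    )
  }
  win <- c(230, 270)
  noise <- c(0, 200)

  clean <- interferenceCheck(mkBlank(), fit, lod = 4, window = win,
                             noiseRegion = noise)
  expect_true(clean$pass)
  expect_length(clean$warnings, 0)

  # quantifier-window peak equivalent to 10 pg/mg with the IS at its
  # nominal area: apparent concentration 10 > LOD 4
  isArea <- 2000 * 3 * sqrt(2 * pi)
  qh <- 0.10 * isArea / (3 * sqrt(2 * pi))  # ratio 0.10 -> 10 pg/mg
  dirty <- interferenceCheck(mkBlank(quantHeight = qh), fit, lod = 4,
                             window = win, noiseRegion = noise)
  expect_false(dirty$pass)
  expect_gt(dirty$perBlank$apparent_pg_per_mg, 8)

  # qualifier-only interference passes quantitation but records a warning
  qual <- interferenceCheck(mkBlank(qualHeight = 500), fit, lod = 4,
                            window = win, noiseRegion = noise)
  expect_true(qual$pass)
  expect_match(qual$warnings, "405>331")
})

test_that("report assembly aggregates pass/fail with reasons", {
  x <- rep(c(6, 10, 20, 30, 60), each = 3)
  set.seed(16)
  tab <- calTable(x, 0.01 * x + rnorm(length(x), 0, 0.005))
  fit <- fitCalibration(tab)
  lin <- linearityVerdict(tab)
  qc <- data.frame(nominal = c(20, 30), scope = "inter_day", n = 9L,
                   mean = c(18.4, 27.8), sd = c(2.6, 2.7),
                   rsd_percent = rsdPercent(c(18.4, 27.8), c(2.6, 2.7)),
                   bias_percent = biasPercent(c(18.4, 27.8), c(20, 30)))
  rep1 <- assembleReport(fit, lin, loq = 6, qc = qc)
  expect_true(rep1@overallPass)

  rep2 <- assembleReport(fit, lin, loq = NA, qc = qc)
  expect_false(rep2@overallPass)
  expect_match(rep2@reasons, "LOQ", all = FALSE)

  expect_error(assembleReport(linearity = lin), "calibration fit")
})

test_that("published inter-day levels all pass the 15%/20% limits", {
  t4 <- loadFixture("validation_table4")
  inter <- t4[t4$scope == "inter_day", ]
  rsd <- rsdPercent(inter$mean_pg_per_mg, inter$sd_pg_per_mg)
  bias <- biasPercent(inter$mean_pg_per_mg, inter$nominal_pg_per_mg)
  expect_true(all(rsd <= 15))
  expect_true(all(abs(bias) <= 20))
})

test_that("serialized reports round RSD to integers and bias to one decimal", {
  x <- rep(c(6, 10, 20, 30, 60), each = 3)
  tab <- calTable(x, 0.01 * x + rep(c(-0.004, 0, 0.004), 5))
  fit <- fitCalibration(tab)
  lin <- linearityVerdict(tab)
  qc <- data.frame(nominal = 30, scope = "inter_day", n = 9L, mean = 27.8,
                   sd = 2.7, rsd_percent = rsdPercent(27.8, 2.7),
                   bias_percent = biasPercent(27.8, 30))
  f <- withr::local_tempfile(fileext = ".json")
  out <- writeValidationReport(assembleReport(fit, lin, loq = 6, qc = qc), f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$qc$rsd_printed, 10)
  expect_equal(back$qc$bias_printed, 7.3)
  expect_true(back$overall_pass)
})
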