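test_that("noise-free traces are exactly the deterministic signal model", {
  spec <- TraceSpec("405>359", duration = 60, samplingInterval = 0.5,
                    baselineLevel = 50, noiseSd = 0,
                    peaks = data.frame(transition = "405>359", rt = 30,
                                       height = 1000, sigma = 2))
  tr <- simulateTraces(spec)[["405>359"]]
  expect_length(tr@times, floor(60 / 0.5) + 1)
  expect_equal(max(tr@intensities), 50 + 1000)
  expect_equal(tr@times[which.max(tr@intensities)], 30)

  flat <- simulateTraces(TraceSpec("405>359", baselineLevel = 50,
                                   noiseSd = 0))[["405>359"]]
  expect_true(all(flat@intensities == 50))
})

test_that("trace noise has the specified SD and baseline mean", {
  spec <- TraceSpec("405>359", duration = 1000, samplingInterval = 0.1,
                    baselineLevel = 500, noiseSd = 100, seed = 7)
  y <- simulateTraces(spec)[["405>359"]]@intensities
  expect_gt(length(y), 10000)
  expect_lt(abs(sd(y) - 100) / 100, 0.05)
  expect_lt(abs(mean(y) - 500), 5)
})

test_that("generators are seed-deterministic and seed-sensitive", {
  mk <- function(seed) simulateTraces(
    TraceSpec("405>359", noiseSd = 10, seed = seed))[["405>359"]]@intensities
  expect_identical(mk(3), mk(3))
  expect_false(identical(mk(3), mk(4)))

  cal <- function(seed) simulateCalibration(
    CalibrationSimSpec(seed = seed))$response_ratio
  expect_identical(cal(11), cal(11))
  expect_false(identical(cal(11), cal(12)))

  coh <- function(seed) simulateCohort(CohortSimSpec(seed = seed))
  expect_identical(coh(5), coh(5))
})

test_that("invalid simulation specs name the offending field", {
  expect_error(TraceSpec("405>359", samplingInterval = 0),
               "samplingInterval")
  expect_error(TraceSpec("405>359", noiseSd = -1), "noiseSd")
  expect_error(TraceSpec("405>359", duration = 10,
                         peaks = data.frame(transition = "405>359", rt = 50,
                                            height = 10, sigma = 1)),
               "retention times")
  expect_error(CalibrationSimSpec(levels = c(10, 6)), "levels")
  expect_error(CalibrationSimSpec(noiseParam = -0.1), "noiseParam")
  expect_error(FactorialSimSpec(trueEffects = c(d = 5)), "unknown effect")
  expect_error(CohortSimSpec(lod = 8, loq = 6), "lod")
})

test_that("noise-free calibration is exactly linear in concentration", {
  tab <- simulateCalibration(CalibrationSimSpec(
    levels = c(6, 10, 20, 30, 60), replicates = 1, slope = 0.01,
    intercept = 0, noiseParam = 0))
  expect_equal(tab$response_ratio, c(0.06, 0.10, 0.20, 0.30, 0.60))
  expect_equal(nrow(simulateCalibration(CalibrationSimSpec())), 15)
})

test_that("curved noise-free calibration is flagged by the Mandel test", {
  tab <- simulateCalibration(CalibrationSimSpec(curvature = 1e-4,
                                                noiseParam = 0))
  res <- mandelTest(tab)
  expect_false(res$pass)
})

test_that("proportional-CV noise reproduces the target CV", {
  tab <- simulateCalibration(CalibrationSimSpec(
    levels = 20, replicates = 1000, noiseModel = "proportional_cv",
    noiseParam = 0.05, seed = 42))
  cv <- sd(tab$response_ratio) / mean(tab$response_ratio)
  expect_lt(abs(cv - 0.05), 0.005)
})

test_that("factorial generator honors effects, order and block count", {
  spec <- FactorialSimSpec(trueEffects = c(a = 0), grandMean = 100,
                           replicateBlocks = 1, noiseSd = 0)
  tab <- simulateFactorial(spec)
  expect_equal(tab$run_label,
               c("0", "a", "b", "ab", "c", "ac", "bc", "abc"))
  expect_true(all(tab$response_pg_per_mg == 100))

  set.seed(1)
  eff <- setNames(rnorm(6, 0, 30),
                  c("a", "b", "c", "ab", "ac", "bc"))
  tab <- simulateFactorial(FactorialSimSpec(trueEffects = eff,
                                            replicateBlocks = 2,
                                            noiseSd = 0))
  expect_equal(nrow(tab), 16)
  est <- estimateEffects(tab, maxOrder = 2)
  expect_equal(est$value[match(names(eff), est$label)], unname(eff),
               tolerance = 1e-12)
})

test_that("cohort generator censors, preserves counts and hits medians", {
  z <- simulateCohort(CohortSimSpec(
    categorySizes = c(Teetotal = 10),
    lognormalParams = data.frame(class = "Teetotal", median = 0, gsd = 2)))
  expect_true(all(z$etg_status == "below_lod"))

  co <- simulateCohort(CohortSimSpec(categorySizes = c(Heavy = 3,
                                                       Teetotal = 6)))
  expect_equal(sum(co$drinking_class == "Heavy"), 3)
  expect_equal(sum(co$drinking_class == "Teetotal"), 6)

  big <- simulateCohort(CohortSimSpec(
    categorySizes = c(Heavy = 2000),
    lognormalParams = data.frame(class = "Heavy", median = 120, gsd = 1.6),
    seed = 9))
  expect_lt(abs(median(big$etg_pg_per_mg, na.rm = TRUE) - 120) / 120, 0.1)
})

test_that("fixtures load with the published shape and round-trip via CSV", {
  doe <- loadFixture("doe_table3")
  expect_equal(nrow(doe), 8)
  expect_equal(doe$response_pg_per_mg[doe$run_label == "0"], 81.8)
  expect_equal(attr(doe, "significanceThreshold"), 19.71)

  cohort <- loadFixture("cohort_table5")
  expect_equal(nrow(cohort), 25)

  srm <- loadFixture("srm_method")
  expect_equal(nrow(srm), 4)
  m <- srmMethodFromTable(srm)
  expect_equal(transitionLabel(quantifier(m)), "405>359")

  expect_error(loadFixture("nope"), "available")

  # round trip: write and re-read reproduces the table field-for-field
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(doe[, c("block", "run_label", "a", "b", "c",
                    "response_pg_per_mg")], f, row.names = FALSE)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$response_pg_per_mg, doe$response_pg_per_mg)
  expect_equal(back$run_label, doe$run_label)
})
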