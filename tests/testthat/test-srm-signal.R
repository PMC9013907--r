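test_that("peak area matches the closed-form Gaussian integral", {
  tr <- gaussTrace(rt = 30, height = 1000, sigma = 2)
  pk <- integratePeak(tr, c(15, 45))
  expect_lt(abs(pk@area - 1000 * 2 * sqrt(2 * pi)) / (1000 * 2 * sqrt(2 * pi)),
            0.01)
  expect_equal(pk@height, 1000, tolerance = 1e-3)
  expect_equal(pk@retentionTime, 30)
})

test_that("a flat zero trace integrates to nothing", {
  tr <- gaussTrace(height = 0)
  pk <- integratePeak(tr, c(15, 45))
  expect_equal(pk@height, 0)
  expect_equal(pk@area, 0)
})

test_that("height and area are invariant under constant baseline offsets", {
  a <- integratePeak(gaussTrace(baseline = 0), c(15, 45))
  b <- integratePeak(gaussTrace(baseline = 500), c(15, 45))
  expect_equal(a@height, b@height)
  expect_equal(a@area, b@area)
})

test_that("half-window integration of a symmetric peak (known baseline) gives half the area", {
  tr <- gaussTrace(rt = 30, height = 1000, sigma = 2, dt = 0.01)
  full <- integratePeak(tr, c(15, 45), baseline = 0)
  half <- integratePeak(tr, c(15, 30), baseline = 0)
  expect_lt(abs(half@area - full@area / 2) / (full@area / 2), 0.02)
})

test_that("integration windows are range- and resolution-checked", {
  tr <- gaussTrace(duration = 60, dt = 0.5)
  expect_error(integratePeak(tr, c(50, 70)), "outside")
  expect_error(integratePeak(tr, c(10, 11)), "fewer than 5")
})

test_that("RMS noise estimation detrends and recovers the noise SD", {
  t <- seq(0, 100, by = 0.02)
  q <- quantifier(etgSrmMethod())
  expect_equal(estimateNoiseRms(SRMTrace(q, t, rep(7, length(t))),
                                c(0, 100)), 0)
  expect_equal(estimateNoiseRms(SRMTrace(q, t, 5 + 3 * t), c(0, 100)), 0,
               tolerance = 1e-8)
  set.seed(2)
  noisy <- SRMTrace(q, t, 100 + rnorm(length(t), 0, 100))
  est <- estimateNoiseRms(noisy, c(0, 100))
  expect_lt(abs(est - 100) / 100, 0.05)
})

test_that("noise regions must avoid declared peaks and have enough samples", {
  tr <- gaussTrace()
  expect_error(estimateNoiseRms(tr, c(0, 20), peakWindows = list(c(15, 45))),
               "overlaps")
  expect_error(estimateNoiseRms(gaussTrace(dt = 1), c(0, 10)),
               "at least 20")
})

test_that("S/N scales inversely with noise on simulated peaks", {
  snrAt <- function(noiseSd) {
    spec <- TraceSpec("405>359", duration = 300, samplingInterval = 0.2,
                      baselineLevel = 100, noiseSd = noiseSd,
                      peaks = data.frame(transition = "405>359", rt = 250,
                                         height = 2000, sigma = 3),
                      seed = 101)
    reps <- vapply(1:100, function(i) {
      spec@seed <- i
      tr <- simulateTraces(spec)[["405>359"]]
      noise <- estimateNoiseRms(tr, c(0, 200),
                                peakWindows = list(c(230, 270)))
      integratePeak(tr, c(230, 270), noiseRms = noise)@snr
    }, numeric(1))
    mean(reps)
  }
  s10 <- snrAt(10)
  s40 <- snrAt(40)
  expect_lt(abs(s10 / s40 - 4) / 4, 0.15)
})

test_that("ion-ratio compliance follows the relative tolerance rule", {
  peaks <- list("405>359" = peakWithArea(1000),
                "405>331" = peakWithArea(400),
                "405>287" = peakWithArea(250))
  ref <- c("405>331" = 0.4, "405>287" = 0.25)
  res <- checkIonRatios(peaks, ref, tolerance = 0.2)
  expect_true(res$pass)

  # interference inflating one qualifier tenfold fails only that qualifier
  peaks[["405>331"]] <- peakWithArea(4000)
  res <- checkIonRatios(peaks, ref, tolerance = 0.2)
  expect_false(res$pass)
  df <- res$qualifiers
  expect_false(df$compliant[df$qualifier == "405>331"])
  expect_true(df$compliant[df$qualifier == "405>287"])

  # |0.61 - 0.5| = 0.11 > 0.20 * 0.5 = 0.10
  res <- checkIonRatios(list("405>359" = peakWithArea(100),
                             "405>331" = peakWithArea(61)),
                        c("405>331" = 0.5), tolerance = 0.2)
  expect_false(res$pass)
})

test_that("missing quantifier errors; missing qualifier is reported absent", {
  expect_error(checkIonRatios(list("405>331" = peakWithArea(10)),
                              c("405>331" = 0.4)), "quantifier")
  res <- checkIonRatios(list("405>359" = peakWithArea(100)),
                        c("405>331" = 0.4))
  expect_false(res$pass)
  expect_equal(res$qualifiers$reason, "absent")
})

test_that("reference ratios are learned as the mean across standards", {
  standards <- list(
    list("405>359" = peakWithArea(100), "405>331" = peakWithArea(40)),
    list("405>359" = peakWithArea(200), "405>331" = peakWithArea(84)))
  ref <- referenceIonRatios(standards)
  expect_equal(unname(ref["405>331"]), mean(c(0.40, 0.42)))
})
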