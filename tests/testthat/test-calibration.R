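test_that("OLS fit reproduces exact and hand-computed lines", {
  x <- c(6, 10, 20, 30, 60)
  fit <- fitCalibration(calTable(x, 0.01 * x))
  expect_equal(fit@slope, 0.01)
  expect_equal(fit@intercept, 0)
  expect_equal(fit@residualSd, 0, tolerance = 1e-12)
  expect_equal(fit@rSquared, 1)

  # hand OLS: points (1,1),(2,2),(3,2) -> slope 1/2, intercept 2/3
  fit2 <- fitCalibration(calTable(1:3, c(1, 2, 2)))
  expect_equal(fit2@slope, 0.5)
  expect_equal(fit2@intercept, 2 / 3)

  # shifting all responses moves the intercept only
  fit3 <- fitCalibration(calTable(1:3, c(1, 2, 2) + 0.25))
  expect_equal(fit3@slope, fit2@slope)
  expect_equal(fit3@intercept, fit2@intercept + 0.25)
})

test_that("OLS agrees with the normal-equations oracle on random tables", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    x <- runif(n, 1, 100)
    y <- runif(n, 0, 2)
    fit <- fitCalibration(calTable(x, y))
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit@intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit@slope, beta[2], tolerance = 1e-10)
  }
})

test_that("fit rejects degenerate designs", {
  expect_error(fitCalibration(calTable(c(1, 1, 2, 2), c(1, 2, 3, 4))),
               "3 distinct")
})

test_that("Fisher homoscedasticity test compares extreme-level variances", {
  tab <- calTable(rep(c(6, 60), each = 3),
                  c(0.06, 0.07, 0.08, 0.60, 0.61, 0.62))
  res <- fisherHomoscedasticityTest(tab)
  expect_equal(res$F, 1)
  expect_true(res$pass)

  # variance ratio 100 with 3 replicates each: F-critical(2,2,0.99) = 99
  set.seed(8)
  lo <- 0.06 + rnorm(3, 0, 0.01)
  hi <- 0.60 + rnorm(3, 0, 0.01) * sqrt(var(lo) * 100 / var(rnorm(3, 0, 0.01)))
  # construct exactly: scale hi residuals for a variance ratio of 100
  r <- c(-1, 0, 1)
  lo <- 0.06 + r * 0.01
  hi <- 0.60 + r * 0.10
  res <- fisherHomoscedasticityTest(calTable(rep(c(6, 60), each = 3),
                                             c(lo, hi)), alpha = 0.01)
  expect_equal(res$F, 100)
  expect_false(res$pass)
  expect_equal(qf(0.99, 2, 2), 99)

  # strongly heteroscedastic simulation over a wide range fails
  tab <- simulateCalibration(CalibrationSimSpec(
    levels = c(6, 300), replicates = 30, noiseModel = "proportional_cv",
    noiseParam = 0.1, seed = 3))
  expect_false(fisherHomoscedasticityTest(tab, alpha = 0.01)$pass)
})

test_that("lack-of-fit splits residual variance correctly", {
  # zero noise, zero curvature: SS_lof = 0, F = 0, pass
  x <- rep(c(6, 10, 20, 30, 60), each = 2)
  res <- lackOfFitTest(calTable(x, 0.01 * x))
  expect_equal(res$F, 0)
  expect_true(res$pass)

  # strong quadratic structure with tiny replicate noise fails
  set.seed(4)
  y <- 0.01 * x + 1e-4 * x^2 + rnorm(length(x), 0, 1e-5)
  res <- lackOfFitTest(calTable(x, y))
  expect_false(res$pass)
  expect_equal(res$df, c(3L, 5L))

  expect_error(lackOfFitTest(calTable(c(6, 10, 20), c(1, 2, 3))),
               "pure error")
})

test_that("Mandel test distinguishes lines from parabolas", {
  x <- c(6, 10, 20, 30, 60)
  res <- mandelTest(calTable(x, 0.01 * x))
  expect_equal(res$F, 0)
  expect_true(res$pass)

  res <- mandelTest(calTable(x, 1e-3 * x^2))
  expect_false(res$pass)
  expect_equal(res$F, Inf)

  expect_error(mandelTest(calTable(1:3, 1:3)), "4 points")
})

test_that("linearity tests hold their type-I error on null data", {
  # quick null check (the full 1000-rep calibration is in the acceptance
  # suite): rejection rate near alpha
  rej <- replicate(200, {
    tab <- simulateCalibration(CalibrationSimSpec(noiseParam = 0.01,
                                                  seed = sample.int(1e6, 1)))
    c(mandel = !mandelTest(tab)$pass, lof = !lackOfFitTest(tab)$pass)
  })
  expect_lt(mean(rej["mandel", ]), 0.12)
  expect_lt(mean(rej["lof", ]), 0.12)
})

test_that("back-calculation inverts the calibration with dilution and mass", {
  fit <- fitCalibration(calTable(c(6, 10, 20, 30, 60),
                                 0.01 * c(6, 10, 20, 30, 60)))
  expect_equal(backCalculate(fit, 0.20), 20)
  expect_equal(backCalculate(fit, 0.20, dilutionFactor = 5), 100)
  expect_equal(backCalculate(fit, fit@intercept), 0)
  expect_equal(backCalculate(fit, 0.20, sampleMass = 25), 40)
  # negative values are preserved, not clamped
  expect_lt(backCalculate(fit, fit@intercept - 0.01), 0)

  # round trip on noise-free synthetic calibrators
  tab <- simulateCalibration(CalibrationSimSpec(intercept = 0.02,
                                                noiseParam = 0))
  fit2 <- fitCalibration(tab)
  expect_equal(backCalculate(fit2, tab$response_ratio),
               tab$nominal_pg_per_mg, tolerance = 1e-8)
})

test_that("dual-range selection routes estimates to the right curve", {
  x1 <- c(6, 10, 20, 30, 60)
  x2 <- c(60, 100, 200, 300)
  low <- fitCalibration(calTable(x1, 0.01 * x1))
  high <- fitCalibration(calTable(x2, 0.01 * x2))
  expect_equal(selectRange(45, low, high)$choice, "low")
  expect_equal(selectRange(127, low, high)$choice, "high")
  expect_equal(selectRange(400, low, high)$choice, "dilution_required")
})

test_that("LOQ is the lowest level within the CV and bias thresholds", {
  expect_equal(determineLoq(data.frame(level = 6, cv_percent = 11,
                                       bias_percent = 6))$loq, 6)
  res <- determineLoq(data.frame(level = c(6, 10, 20),
                                 cv_percent = c(25, 25, 25),
                                 bias_percent = c(5, 5, 5)))
  expect_false(res$defined)
  expect_equal(determineLoq(data.frame(level = c(6, 10),
                                       cv_percent = c(21, 8),
                                       bias_percent = c(5, 4)))$loq, 10)
  expect_error(determineLoq(data.frame(level = numeric(),
                                       cv_percent = numeric(),
                                       bias_percent = numeric())), "empty")
})
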