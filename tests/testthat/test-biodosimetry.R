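test_that("calibration fitting recovers exact lines and rejects bad input", {
  pts <- data.frame(dose_gy = c(0, 1, 2, 4), mean_foci = 2 * c(0, 1, 2, 4) + 1)
  cv <- fitCalibration(pts)
  expect_equal(calSlope(cv), 2, tolerance = 1e-12)
  expect_equal(calIntercept(cv), 1, tolerance = 1e-12)
  expect_equal(calRSquared(cv), 1, tolerance = 1e-12)
  expect_equal(doseRange(cv), c(0, 4))
  expect_equal(cv@nPoints, 4L)

  expect_error(fitCalibration(pts[1:2, ]), "at least 3")
  expect_error(fitCalibration(data.frame(dose_gy = c(1, 1, 1),
                                         mean_foci = c(1, 2, 3))),
               "not all be equal")
})

test_that("OLS equals the closed-form normal-equations oracle", {
  for (s in 1:5) {
    set.seed(400 + s)
    x <- c(0, 1, 2, 4, 6)
    y <- 1.9 * x + 0.8 + rnorm(5, sd = 0.3)
    cv <- fitCalibration(data.frame(dose_gy = x, mean_foci = y))
    # independent closed-form solution
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    a <- sum((x - mean(x)) * (y - mean(y))) / sxx
    b <- mean(y) - a * mean(x)
    res <- y - (a * x + b)
    s2 <- sum(res^2) / (n - 2)
    se_a <- sqrt(s2 / sxx)
    se_b <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    expect_equal(calSlope(cv), a, tolerance = 1e-10)
    expect_equal(calIntercept(cv), b, tolerance = 1e-10)
    expect_equal(cv@seA, se_a, tolerance = 1e-10)
    expect_equal(cv@seB, se_b, tolerance = 1e-10)
    expect_equal(calRSquared(cv), r2, tolerance = 1e-10)
  }
})

test_that("fits on simulated count data recover the generating line", {
  # ground-truth counts (no imaging): over many seeds the fitted slope
  # and intercept are unbiased for the generating values
  cfg <- SceneConfig()
  doses <- c(0, 1, 2, 4)
  slopes <- numeric(24); intercepts <- numeric(24)
  for (s in seq_along(slopes)) {
    set.seed(500 + s)
    pts <- data.frame(
      dose_gy = doses,
      mean_foci = vapply(doses, function(d)
        mean(sampleFocusCount(d, cfg, n = 200)), numeric(1)))
    cv <- fitCalibration(pts)
    slopes[s] <- calSlope(cv); intercepts[s] <- calIntercept(cv)
    expect_lt(abs(calSlope(cv) - 1.996), 4 * cv@seA + 0.05)
  }
  expect_lt(abs(mean(slopes) - 1.996),
            3 * stats::sd(slopes) / sqrt(length(slopes)))
  expect_lt(abs(mean(intercepts) - 0.769),
            3 * stats::sd(intercepts) / sqrt(length(intercepts)))
})

test_that("forward prediction and dose inversion are exact inverses", {
  cv <- new("CalibrationCurve", slopeA = 1.996, interceptB = 0.769,
            rSquared = 0.97, seA = 0.1, seB = 0.1,
            doseRangeGy = c(0, 4), nPoints = 4L)
  expect_equal(predictFoci(cv, 0), 0.769)
  expect_equal(predictFoci(cv, 2), 4.761)
  flat <- new("CalibrationCurve", slopeA = 0, interceptB = 3,
              rSquared = NA_real_, seA = 0, seB = 0,
              doseRangeGy = c(0, 4), nPoints = 4L)
  expect_equal(predictFoci(flat, 5), 3)
  expect_error(estimateDose(flat, 3), "slope is zero")

  expect_equal(estimateDose(cv, 0.769)$estimated_dose_gy, 0)
  for (d in c(-0.5, 0, 1, 3, 6))
    expect_equal(estimateDose(cv, predictFoci(cv, d))$estimated_dose_gy, d,
                 tolerance = 1e-12)

  simple <- new("CalibrationCurve", slopeA = 2, interceptB = 1,
                rSquared = 1, seA = 0, seB = 0, doseRangeGy = c(0, 4),
                nPoints = 4L)
  expect_equal(estimateDose(simple, 5)$estimated_dose_gy, 2)

  # negative estimates are preserved by default, clamped on request
  est <- estimateDose(cv, 0.2, actualDoseGy = 0)
  expect_lt(est$estimated_dose_gy, 0)
  expect_true(est$extrapolated)
  expect_equal(est$mad_gy, abs(est$estimated_dose_gy))
  expect_equal(estimateDose(cv, 0.2, truncateAtZero = TRUE)$estimated_dose_gy,
               0)

  # extrapolation flag outside the 0-4 Gy calibration range
  expect_true(estimateDose(cv, predictFoci(cv, 6))$extrapolated)
  expect_false(estimateDose(cv, predictFoci(cv, 3))$extrapolated)
})

test_that("absolute dose error behaves like a metric", {
  expect_equal(doseMAD(2.75, 2), 0.75)
  expect_equal(doseMAD(-0.52, 0), 0.52)
  expect_equal(doseMAD(3, 3), 0)
  expect_error(doseMAD(Inf, 0), "finite")
  set.seed(31)
  for (i in 1:25) {
    x <- runif(3, -2, 8)
    expect_equal(doseMAD(x[1], x[2]), doseMAD(x[2], x[1]))
    expect_lte(doseMAD(x[1], x[3]),
               doseMAD(x[1], x[2]) + doseMAD(x[2], x[3]) + 1e-12)
  }
})

test_that("average MAD reproduces printed two-decimal summaries", {
  expect_equal(roundHalfUp(averageMAD(c(0.27, 0.75, 0.31, 0.89)), 2), 0.56)
  expect_equal(roundHalfUp(averageMAD(c(0.52, 0.93, 0.67, 0.36)), 2), 0.62)
  expect_equal(averageMAD(c(0, 0)), 0)
  expect_error(averageMAD(numeric(0)), "at least one")
  expect_error(averageMAD(c(0.3, -0.1)), "non-negative")
})

test_that("calibration curves survive a JSON round-trip", {
  cv <- new("CalibrationCurve", slopeA = 1.739, interceptB = 1.08,
            rSquared = 0.913, seA = 0.21, seB = 0.47,
            doseRangeGy = c(0, 4), nPoints = 4L)
  p <- withr::local_tempfile(fileext = ".json")
  writeCalibration(cv, p)
  cv2 <- readCalibration(p)
  for (sl in c("slopeA", "interceptB", "rSquared", "seA", "seB"))
    expect_equal(slot(cv2, sl), slot(cv, sl))
  expect_equal(cv2@doseRangeGy, cv@doseRangeGy)
  expect_equal(cv2@nPoints, cv@nPoints)
})
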