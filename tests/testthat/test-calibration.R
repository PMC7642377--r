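# Conversion fitting, estimation and agreement statistics.

test_that("exact collinear data recover slope and intercept exactly", {
  fit <- fitConversion(c(1, 2, 3), c(3, 5, 7))
  expect_equal(fit$mS, 2, tolerance = 1e-12)
  expect_equal(fit$bS, 1, tolerance = 1e-12)
})

test_that("degenerate fit inputs raise specific conditions", {
  expect_error(fitConversion(c(1, 2), c(1, 2)), class = "insufficientDataError")
  expect_error(fitConversion(rep(2, 5), 1:5), class = "degeneratePredictorError")
  expect_error(fitConversion(1:4, 1:3), class = "validationError")
})

test_that("noisy linear panels recover the generating coefficients", {
  # simulation truth: a partial-volume-like conversion with slope 5.774
  # and intercept 1.07 L, Gaussian noise 0.5 L, cohort-sized sample
  set.seed(424242)
  n <- 193
  s <- runif(n, 0.8, 3.2)
  v <- 5.774 * s + 1.07 + rnorm(n, 0, 0.5)
  fit <- fitConversion(s, v)
  # closed-form OLS oracle
  mHat <- sum((s - mean(s)) * (v - mean(v))) / sum((s - mean(s))^2)
  bHat <- mean(v) - mHat * mean(s)
  expect_equal(fit$mS, mHat, tolerance = 1e-10)
  expect_equal(fit$bS, bHat, tolerance = 1e-10)
  seSlope <- 0.5 / sqrt(sum((s - mean(s))^2))
  expect_lt(abs(fit$mS - 5.774), 3 * seSlope)
})

test_that("volume estimation applies the conversion equation", {
  expect_equal(estimateVolume(1.00, 5.774, 1.07), 6.844)
  expect_equal(estimateVolume(50, 0.198, 4.74), 14.64)
  expect_equal(estimateVolume(0, 3.3, 2.2), 2.2)
  expect_warning(est <- estimateVolume(-100, 0.2, 1), "negative")
  expect_equal(est, -19)
})

test_that("agreement statistics match hand-computed worked examples", {
  # perfect agreement
  ag <- agreementStats(c(8, 10, 12), c(8, 10, 12))
  expect_equal(ag$sDpct, 0)
  expect_equal(ag$meanDpct, 0)
  expect_equal(ag$rP, 1)

  # d% = (+10, -10): sample SD = sqrt(2)*10
  ag2 <- agreementStats(c(11, 9), c(10, 10))
  expect_equal(ag2$meanDpct, 0, tolerance = 1e-9)
  expect_equal(ag2$sDpct, sqrt(200), tolerance = 1e-9)

  # differences (0, 1, 2): limits 1 +/- 1.96 * 1
  ag3 <- agreementStats(c(10, 11, 12), c(10, 10, 10))
  expect_equal(ag3$loaLow, -0.96, tolerance = 1e-9)
  expect_equal(ag3$loaHigh, 2.96, tolerance = 1e-9)

  expect_error(agreementStats(c(1, 2), c(1, 0)), class = "invalidReferenceError")
  expect_error(agreementStats(1, 1), class = "insufficientDataError")
})

test_that("R squared equals the squared Pearson correlation of a linear fit", {
  set.seed(7)
  for (i in 1:5) {
    s <- rnorm(40, 10, 3)
    v <- 2 + 0.8 * s + rnorm(40, 0, 1.5)
    fit <- fitConversion(s, v)
    ag <- agreementStats(estimateVolume(s, fit$mS, fit$bS), v)
    # independent route: R^2 from the regression ANOVA decomposition
    res <- v - (fit$mS * s + fit$bS)
    r2lm <- 1 - sum(res^2) / sum((v - mean(v))^2)
    expect_equal(ag$rSquared, ag$rP^2, tolerance = 1e-9)
    expect_equal(ag$rSquared, r2lm, tolerance = 1e-9)
    # OLS residuals average zero, so the Bland-Altman mean difference is 0
    expect_equal(mean(estimateVolume(s, fit$mS, fit$bS) - v), 0, tolerance = 1e-9)
  }
})

test_that("percent-difference SD is invariant under common volume rescaling", {
  set.seed(11)
  s <- runif(30, 1, 4)
  v <- 4 * s + 2 + rnorm(30, 0, 0.6)
  sdpct <- function(s, v) {
    fit <- fitConversion(s, v)
    agreementStats(estimateVolume(s, fit$mS, fit$bS), v)$sDpct
  }
  expect_equal(sdpct(s, v), sdpct(s, 3.7 * v), tolerance = 1e-9)
})

test_that("slope and intercept estimates are unbiased across Monte-Carlo replicates", {
  set.seed(3131)
  nrep <- 200
  ms <- numeric(nrep); bs <- numeric(nrep)
  s <- runif(60, 0.8, 3.2)
  for (i in seq_len(nrep)) {
    v <- 5.774 * s + 1.07 + rnorm(60, 0, 0.5)
    fit <- fitConversion(s, v)
    ms[i] <- fit$mS; bs[i] <- fit$bS
  }
  expect_lt(abs(mean(ms) - 5.774), 2 * sd(ms) / sqrt(nrep))
  expect_lt(abs(mean(bs) - 1.07), 2 * sd(bs) / sqrt(nrep))
})

test_that("cohort calibration emits one row per surrogate and group", {
  panel <- exactPanel(12)
  calib <- calibrateCohort(panel)
  expect_identical(nrow(calib), 18L)
  expect_setequal(unique(calib$group), c("female", "male", "total"))
  # the panel is exactly linear in every surrogate
  expect_true(all(abs(calib$r_squared - 1) < 1e-9))
  expect_true(all(calib$s_dpct < 1e-6))

  fOnly <- calibrateCohort(panel[panel$sex == "female", ], groups = "female")
  expect_identical(nrow(fOnly), 6L)
})

test_that("rows without a reference volume are excluded, small groups skipped", {
  panel <- exactPanel(10)
  panel$v_asat_L[panel$sex == "male"] <- NA
  expect_warning(
    calib <- suppressMessages(calibrateCohort(panel, groups = c("male", "total"))),
    "skipped")
  expect_setequal(unique(calib$group), "total")
  expect_true(all(calib$n == sum(!is.na(panel$v_asat_L))))
})
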