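test_that("maxSlope matches analytic derivatives", {
  ## linear ramp: derivative is the slope everywhere
  expect_equal(maxSlope(intensityTimeCurve(0:10, 2 + 5 * (0:10))), 5)
  ## constant curve: zero
  expect_equal(maxSlope(intensityTimeCurve(0:10, rep(3, 11))), 0)

  ## gamma-variate with known parameters: the analytic maximum of the
  ## derivative, attained at x = beta * (alpha - sqrt(alpha))
  alpha <- 3; beta <- 1.8; K <- 2.5; t0 <- 2
  t <- seq(0, 30, by = 0.1)
  x <- pmax(t - t0, 0)
  curve <- intensityTimeCurve(t, K * x^alpha * exp(-x / beta))
  xs <- beta * (alpha - sqrt(alpha))
  analytic <- K * exp(-xs / beta) * xs^(alpha - 1) * (alpha - xs / beta)
  expect_equal(maxSlope(curve), analytic, tolerance = 1e-3)

  ## non-uniform sampling is rejected at construction
  expect_error(intensityTimeCurve(c(0, 1, 3), c(1, 2, 3)), "uniform")
})

test_that("nidusMeanDiameter averages the four view diameters", {
  expect_equal(nidusMeanDiameter(c(2, 2, 2, 2)), 2)
  expect_equal(nidusMeanDiameter(1, 3, 1, 3), 2)
  expect_equal(nidusMeanDiameter(2.0, 3.0, 2.5, 4.1), 2.9)
  expect_error(nidusMeanDiameter(2, 3, 2.5), "four")
  expect_error(nidusMeanDiameter(2, -3, 2.5, 4), "positive")
})

test_that("correlateFD reproduces the textbook Pearson formula", {
  ## exact collinearity
  out <- correlateFD(1:10, 2 * (1:10) + 3)
  expect_equal(out$r, 1)
  expect_lt(out$p, 1e-12)
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 3)
  expect_equal(correlateFD(1:10, -(1:10))$r, -1)

  ## hand-expanded formula on 10 fixed pairs
  fd <- c(1.11, 1.09, 1.18, 1.22, 1.08, 1.31, 1.15, 1.27, 1.12, 1.24)
  cov <- c(3.2, 2.9, 4.1, 4.4, 2.7, 5.4, 3.8, 4.9, 3.1, 4.6)
  n <- 10
  rHand <- (n * sum(fd * cov) - sum(fd) * sum(cov)) /
    sqrt((n * sum(fd^2) - sum(fd)^2) * (n * sum(cov^2) - sum(cov)^2))
  tHand <- rHand * sqrt((n - 2) / (1 - rHand^2))
  pHand <- 2 * pt(-abs(tHand), n - 2)
  out <- correlateFD(fd, cov)
  expect_equal(out$r, rHand, tolerance = 1e-10)
  expect_equal(out$p, pHand, tolerance = 1e-8)
  expect_equal(out$n, 10L)

  expect_error(correlateFD(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlateFD(c(1, 2), c(1, 2)), "at least 3")
})

test_that("sampleSizeFromR applies the Fisher-z formula", {
  ## the study's contrast-transit correlation for the box dimension
  expect_identical(sampleSizeFromR(0.913), 7L)
  ## near-perfect correlation: the formula floors at 3 + 1
  expect_identical(sampleSizeFromR(0.9999), 4L)
  ## moderate correlation; ceiling of 29.01
  expect_identical(sampleSizeFromR(0.5), 30L)
  ## sign does not matter
  expect_identical(sampleSizeFromR(-0.913), 7L)
  expect_error(sampleSizeFromR(1), "r must")
  expect_error(sampleSizeFromR(0), "r must")
})

test_that("compareHemispheres summarizes paired contrasts", {
  ## identical halves: all paired differences are zero, SEM of a constant
  ## column is zero
  subj <- sprintf("P%02d", 1:4)
  fdTable <- rbind(
    data.frame(subject = subj, group = "patient", region = "AVM",
               method = "Db", value = 1.2),
    data.frame(subject = subj, group = "patient", region = "noAVM",
               method = "Db", value = 1.2))
  out <- compareHemispheres(fdTable)
  expect_equal(out$paired$meanDiff, 0)
  expect_equal(out$paired$semDiff, 0)
  expect_equal(out$summary$sem, rep(0, 2))

  ## a known difference is recovered with the right sign and t statistic
  fdTable$value[fdTable$region == "AVM"] <- c(1.25, 1.30, 1.28, 1.27)
  out2 <- compareHemispheres(fdTable)
  diffs <- c(0.05, 0.10, 0.08, 0.07)
  expect_equal(out2$paired$meanDiff, mean(diffs))
  tt <- t.test(diffs)
  expect_equal(out2$paired$t, unname(tt$statistic))

  expect_error(compareHemispheres(data.frame(subject = 1)), "columns")
  bad <- fdTable[-5, ]  # one subject lost its noAVM hemisphere
  expect_error(compareHemispheres(bad), "missing hemisphere")
})

test_that("runStudy produces a complete, reproducible report", {
  cfg <- list(nPatients = 3, nControls = 3, seed = 2,
              noise = list(slopeSD = 0, diamSD = 0))
  rep1 <- runStudy(cfg)
  expect_s4_class(rep1, "CohortReport")

  ## shape contract: (2 hemispheres + 1 whole) x 5 methods x 6 subjects
  expect_equal(nrow(rep1@fdTable), 6 * 3 * 5)
  expect_setequal(unique(rep1@fdTable$method),
                  c("Db", "Dm", "D0", "D1", "D2"))
  expect_setequal(unique(rep1@fdTable$region),
                  c("AVM", "noAVM", "left", "right", "total"))
  expect_equal(nrow(rep1@correlations), 10)  # 5 methods x 2 covariates
  expect_true(all(abs(rep1@correlations$r) <= 1))
  expect_true(all(rep1@sampleSizes$n >= 4))

  ## determinism: identical config, identical report
  rep2 <- runStudy(cfg)
  expect_identical(rep1@fdTable, rep2@fdTable)
  expect_identical(rep1@correlations, rep2@correlations)

  ## byte-identical CSV output on rerun
  d1 <- file.path(tempdir(), "study1"); d2 <- file.path(tempdir(), "study2")
  runStudy(c(cfg, list(outputDir = d1)))
  runStudy(c(cfg, list(outputDir = d2)))
  for (f in c("report.csv", "correlations.csv", "summary.txt")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("control hemispheres are symmetric on average", {
  rep <- runStudy(list(nPatients = 2, nControls = 10, seed = 4,
                       noise = list(slopeSD = 0, diamSD = 0)))
  ctrl <- rep@pairedTests[rep@pairedTests$contrast == "control left - right", ]
  ## left-right differences centred at zero: small and not significant
  expect_true(all(abs(ctrl$meanDiff) < 0.02))
  expect_true(all(ctrl$p > 0.01))
})
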