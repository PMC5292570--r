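# Evaluation analyses and reference-table summaries.

test_that("RMS envelope has the right closed-form values", {
  fs <- 1600
  const <- MeasurementTrace(matrix(3, 3200, 1), fs = fs)
  expect_true(all(abs(rmsEnvelope(const) - 3) < 1e-12))
  zero <- MeasurementTrace(matrix(0, 3200, 1), fs = fs)
  expect_true(all(rmsEnvelope(zero) == 0))
  # 50 Hz unit sinusoid, 160 ms window = 8 full periods -> RMS 1/sqrt(2)
  t <- (0:3199) / fs
  tone <- MeasurementTrace(matrix(sin(2 * pi * 50 * t)), fs = fs)
  env <- rmsEnvelope(tone, windowMs = 160)
  expect_equal(unname(env[, 1]), rep(1 / sqrt(2), nrow(env)), tolerance = 1e-9)
})

test_that("excluded samples are skipped by the RMS envelope", {
  x <- rep(1, 3200)
  x[1001:1200] <- 100
  mask <- rep(FALSE, 3200); mask[1001:1200] <- TRUE
  tr <- MeasurementTrace(matrix(x), fs = 1600, excluded = mask)
  env <- rmsEnvelope(tr)
  # windows with retained samples ignore the excluded burst; fully-excluded
  # windows are NA
  expect_true(all(abs(env[!is.na(env)] - 1) < 1e-12))
  expect_true(any(is.na(env)))
})

test_that("pearson correlation behaves canonically", {
  set.seed(3)
  x <- rnorm(200)
  expect_equal(pearsonCorr(x, x)$r, 1)
  expect_equal(pearsonCorr(x, -x)$r, -1)
  expect_equal(pearsonCorr(2 * x + 5, x)$r, pearsonCorr(x, x)$r)
  expect_error(pearsonCorr(x, rep(1, 200)), "zero variance")
  expect_error(pearsonCorr(x, x[1:10]), "equal length")
})

test_that("two electrode views of one source correlate, degrading with noise", {
  model <- SourceModel()
  src <- synthSource(model, "flexion", 2, seed = 61)
  rs <- vapply(c(2e-7, 2e-6, 6e-6), function(nd) {
    wet <- applyElectrode(src, wetTransfer(noiseDensity = nd), seed = 71)
    ppy <- applyElectrode(src, ppyTransfer(noiseDensity = nd), seed = 72)
    pearsonCorr(rmsEnvelope(wet)[, 1], rmsEnvelope(ppy)[, 1])$r
  }, numeric(1))
  expect_gt(rs[1], 0.95)
  expect_true(all(diff(rs) < 0))
})

test_that("mean/SD summaries reproduce the printed headline values", {
  corr <- referenceTable("correlations")
  s <- meanSd(corr$r)
  expect_equal(myobench:::roundHalfUp(s[["mean"]], 2), 0.87)
  expect_equal(myobench:::roundHalfUp(s[["sd"]], 3), 0.065)

  imp <- referenceTable("impedance")
  l1 <- meanSd(imp$mag_ohm[imp$level == 1])
  expect_equal(myobench:::roundHalfUp(l1[["mean"]], 0), 1560)
  expect_equal(myobench:::roundHalfUp(l1[["sd"]], 0), 1047)

  expect_equal(unname(meanSd(rep(4.2, 5))[["sd"]]), 0)
  expect_error(meanSd(numeric(0)), "empty")
})

test_that("every printed summary cell reproduces from the per-trial tables", {
  tab <- reproduceTables()
  expect_true(all(tab$match))
  # the known sub-precision cell: values average 1.14 but print as 1.2
  phase1 <- tab[tab$quantity == "imp_phase_mean_level1", ]
  expect_equal(phase1$computed, 1.14, tolerance = 1e-9)
  expect_lt(abs(phase1$computed - phase1$printed), 0.1 + 1e-9)
})

test_that("accuracy summaries give the printed condition means", {
  acc <- referenceTable("accuracy")
  s <- accuracySummary(acc)
  overall <- setNames(s$overall$accuracy, s$overall$electrode)
  expect_equal(myobench:::roundHalfUp(overall[["wet"]], 1), 88.9)
  expect_equal(myobench:::roundHalfUp(overall[["ppy"]], 1), 88.4)

  # exchangeability: permuting subject order changes nothing
  perm <- acc[sample(nrow(acc)), ]
  s2 <- accuracySummary(perm)
  expect_equal(sort(s2$perTask$accuracy), sort(s$perTask$accuracy))
  expect_equal(s2$overall$accuracy[order(s2$overall$electrode)],
               s$overall$accuracy[order(s$overall$electrode)])

  all100 <- acc; all100$accuracy <- 100
  expect_true(all(accuracySummary(all100)$overall$accuracy == 100))
  incomplete <- acc[-1, ]
  expect_error(accuracySummary(incomplete), "balanced")
})

test_that("noise-level classification follows the peak bands", {
  expect_equal(classifyNoiseLevel(MeasurementTrace(matrix(0.01, 1600, 1), fs = 1600)), 1L)
  clipped <- MeasurementTrace(matrix(9 * sign(sin(1:1600)), ncol = 1), fs = 1600)
  expect_equal(classifyNoiseLevel(clipped), 3L)
  mid <- MeasurementTrace(matrix(4 * sin((1:1600) / 20), ncol = 1), fs = 1600)
  expect_equal(classifyNoiseLevel(mid), 2L)
})

test_that("simulated rest traces recover their noise level for most seeds", {
  cfg <- defaultExperimentConfig()
  recovered <- sapply(1:3, function(lv) {
    sapply(1:20, function(k) {
      st <- drawImpedanceStates(cfg$noiseLevels[[lv]], 1, seed = 3000 * lv + k)[[1]]
      src <- synthSource(cfg$source, "relax", 1, seed = 5000 + k)
      out <- simulateMeasurement(src, cfg$interference, st, cfg$amplifier, cfg$filter)
      classifyNoiseLevel(out)
    })
  })
  for (lv in 1:3) expect_gt(mean(recovered[, lv] == lv), 0.5)
})

test_that("band-power comparison matches the periodogram oracle", {
  set.seed(9)
  a <- MeasurementTrace(matrix(rnorm(3200)), fs = 1600)
  same <- bandPowerCompare(a, a)
  expect_equal(unname(same$ratioBoverA), c(1, 1))

  src <- synthSource(SourceModel(), "close", 2, seed = 81)
  wet <- applyElectrode(src, wetTransfer(noiseDensity = 0))
  ppy <- applyElectrode(src, ppyTransfer(noiseDensity = 0))
  cmp <- bandPowerCompare(wet, ppy, splitHz = 150)
  expect_gt(cmp$ratioBoverA[["above"]], cmp$ratioBoverA[["below"]])

  # one-sided periodogram oracle in plain arithmetic
  xa <- traceSamples(a)[, 1]
  n <- length(xa)
  p <- (Mod(fft(xa))^2 / n)[1:(n / 2 + 1)]
  f <- (0:(n / 2)) * 1600 / n
  expect_equal(sum(p[f > 0 & f <= 150]), same$a[["below"]], tolerance = 1e-9)
  expect_equal(sum(p[f > 150]), same$a[["above"]], tolerance = 1e-9)
})

test_that("rest-state harmonic noise power increases with the level", {
  cfg <- defaultExperimentConfig()
  powers <- sapply(1:3, function(lv) {
    mean(sapply(1:20, function(k) {
      st <- drawImpedanceStates(cfg$noiseLevels[[lv]], 1, seed = 7000 * lv + k)[[1]]
      src <- synthSource(cfg$source, "relax", 1, seed = 9000 + k)
      out <- simulateMeasurement(src, cfg$interference, st, cfg$amplifier, cfg$filter)
      myobench:::harmonicBandPower(out)
    }))
  })
  expect_true(all(diff(powers) > 0))
})
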