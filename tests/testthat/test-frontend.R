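# Measurement-electronics simulation.

test_that("imbalance indices match the polar-arithmetic oracle", {
  balanced <- ImpedanceState(5e4, -20, 5e4, -20, r1 = 1000, r2 = 1000)
  expect_equal(unname(imbalanceIndices(balanced)), c(0, 0))

  # construction realizing the first tabulated level-1 pair
  st <- ImpedanceState(50000, -20, 51300, -19.4)
  idx <- imbalanceIndices(st)
  expect_equal(idx[["magDiff"]], 1300)
  expect_equal(idx[["phaseDiff"]], 0.6)

  set.seed(31)
  for (i in 1:20) {
    z1m <- runif(1, 1e3, 1e5); z1p <- runif(1, -80, 10)
    z2m <- runif(1, 1e3, 1e5); z2p <- runif(1, -80, 10)
    r1 <- runif(1, 0, 2e5); r2 <- runif(1, 0, 2e5)
    st <- ImpedanceState(z1m, z1p, z2m, z2p, r1, r2)
    z1 <- z1m * exp(1i * z1p * pi / 180) + r1
    z2 <- z2m * exp(1i * z2p * pi / 180) + r2
    expect_equal(unname(imbalanceIndices(st)),
                 c(abs(Mod(z1) - Mod(z2)), abs(Arg(z1) - Arg(z2)) * 180 / pi))
  }
})

test_that("common-mode coupling vanishes for a balanced ideal amplifier", {
  st <- ImpedanceState(5e4, -20, 5e4, -20)
  expect_equal(Mod(commonModeCoupling(st, AmplifierSpec(intrinsicCmrrDb = Inf))), 0)
  expect_equal(Mod(commonModeCoupling(st, AmplifierSpec(intrinsicCmrrDb = 100))), 1e-5)
})

test_that("coupling magnitude grows with the complex arm difference", {
  amp <- AmplifierSpec(intrinsicCmrrDb = Inf)
  gOf <- function(r2) Mod(commonModeCoupling(ImpedanceState(5e4, -20, 5e4, -20,
                                                            r2 = r2), amp))
  g <- vapply(seq(0, 2e5, length.out = 9), gOf, numeric(1))
  expect_true(all(diff(g) > 0))

  specs <- noiseLevelSpecs()
  meanState <- function(sp) ImpedanceState(5e4 - sp@magDiffMean / 2,
                                           -20 - sp@phaseDiffMean / 2,
                                           5e4 + sp@magDiffMean / 2,
                                           -20 + sp@phaseDiffMean / 2)
  gl <- vapply(specs, function(sp) Mod(commonModeCoupling(meanState(sp),
                                                          benchAmplifier())),
               numeric(1))
  expect_true(gl[1] < gl[2] && gl[2] < gl[3])
})

test_that("the simulated chain is silent, linear below rails, and clips at them", {
  fs <- 1600
  filt <- FilterChainSpec(fs = fs)
  amp <- benchAmplifier()
  balanced <- ImpedanceState(5e4, -20, 5e4, -20)
  zero <- MeasurementTrace(matrix(0, 3200, 1), fs = fs)
  out0 <- simulateMeasurement(zero, silentInterference(), balanced, amp, filt)
  expect_equal(max(abs(traceSamples(out0))), 0)

  small <- MeasurementTrace(matrix(1e-4 * sin(2 * pi * 100 * (0:3199) / fs)), fs = fs)
  double <- MeasurementTrace(2 * traceSamples(small), fs = fs)
  o1 <- traceSamples(simulateMeasurement(small, silentInterference(), balanced, amp, filt))
  o2 <- traceSamples(simulateMeasurement(double, silentInterference(), balanced, amp, filt))
  expect_equal(o2, 2 * o1, tolerance = 1e-9)

  big <- MeasurementTrace(matrix(0.05 * sin(2 * pi * 100 * (0:3199) / fs)), fs = fs)
  ob <- traceSamples(simulateMeasurement(big, silentInterference(), balanced, amp, filt))
  expect_equal(max(ob), 9)
  expect_equal(min(ob), -9)
  expect_true(all(abs(ob) <= 9))
})

test_that("imbalance lifts mains harmonics above the balanced residual floor", {
  fs <- 1600
  filt <- FilterChainSpec(fs = fs)
  amp <- benchAmplifier()
  zero <- MeasurementTrace(matrix(0, 3200, 1), fs = fs)
  interf <- InterferenceModel()
  balanced <- ImpedanceState(5e4, -20, 5e4, -20)
  sp3 <- noiseLevelSpecs()[[3]]
  unbal <- ImpedanceState(5e4 - sp3@magDiffMean / 2, -20 - sp3@phaseDiffMean / 2,
                          5e4 + sp3@magDiffMean / 2, -20 + sp3@phaseDiffMean / 2)
  pow <- function(st) {
    x <- traceSamples(simulateMeasurement(zero, interf, st, amp, filt))[, 1]
    sum(sapply(c(100, 150, 200, 250, 300), function(f0)
      oracleBandPower(x, fs, f0 - 2, f0 + 2)))
  }
  expect_gt(pow(unbal) / (pow(balanced) + 1e-30), 100)
})

test_that("the notch removes 50 Hz and the passband is flat from 10 to 500 Hz", {
  fs <- 1600
  filt <- FilterChainSpec(fs = fs)
  gainAt <- function(f0) {
    t <- (0:(8 * fs - 1)) / fs
    y <- myobench:::applyFilterChain(sin(2 * pi * f0 * t), filt)
    core <- (fs + 1):(7 * fs)  # drop edge transients
    sqrt(mean(y[core]^2)) / sqrt(0.5)
  }
  expect_lt(20 * log10(gainAt(50)), -30)
  for (f0 in c(10, 200, 500))
    expect_lt(abs(20 * log10(gainAt(f0))), 1)
})

test_that("the meter tone saturates the output and is excluded with its margin", {
  fs <- 1600
  amp <- benchAmplifier()
  interf <- InterferenceModel(meterSchedule = matrix(c(2, 2.5), ncol = 2))
  tr <- MeasurementTrace(matrix(0, 5 * fs, 1), fs = fs)
  out <- applyMeterSchedule(tr, interf, amp, settlingMarginS = 0.05)
  mask <- excludedMask(out)
  expect_equal(mean(mask), (0.5 + 2 * 0.05) / 5, tolerance = 0.002)
  on <- traceSamples(out)[seq(2 * fs + 1, 2.5 * fs), 1]
  expect_equal(max(abs(on)), 9)
  # hard clipping except the 2-in-16 samples landing on exact tone zeros
  expect_gte(mean(abs(on) > 8.9), 14 / 16 - 0.01)
  # samples outside the masked region untouched
  expect_true(all(traceSamples(out)[!mask, 1] == 0))

  empty <- applyMeterSchedule(tr, InterferenceModel(), amp)
  expect_identical(excludedMask(empty), rep(FALSE, 5 * fs))
  expect_identical(traceSamples(empty), traceSamples(tr))
})

test_that("saturated-run exclusion matches a brute-force scan", {
  v <- rep(0, 1000)
  v[301:500] <- 9
  tr <- excludeSaturated(MeasurementTrace(v, fs = 1600), thresholdV = 8.9,
                         minRun = 50)
  expect_identical(which(excludedMask(tr)), 301:500)

  clean <- excludeSaturated(MeasurementTrace(v / 100, fs = 1600), 8.9, 50)
  expect_false(any(excludedMask(clean)))

  set.seed(17)
  for (i in 1:10) {
    x <- pmin(pmax(rnorm(600, sd = 6), -9), 9)
    tr <- excludeSaturated(MeasurementTrace(x, fs = 1600), 8.99, minRun = 3)
    expect_identical(excludedMask(tr), oracleRunMask(abs(x) >= 8.99, 3))
  }
})
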