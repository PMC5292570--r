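# Synthetic source generator and electrode transfers.

test_that("source RMS tracks the motion envelope and the rest class is silent", {
  model <- SourceModel()
  close <- traceSamples(synthSource(model, "close", 2, seed = 7))
  relax <- traceSamples(synthSource(model, "relax", 2, seed = 7))
  post <- -(1:200)  # drop the onset ramp
  rmsOracle <- function(v) sqrt(sum(v^2) / length(v))
  closeRms <- apply(close[post, ], 2, rmsOracle)
  expect_true(all(abs(closeRms / model@envelope["close", ] - 1) < 0.1))
  expect_true(all(apply(relax[post, ], 2, rmsOracle) <= 0.05 * max(closeRms)))
})

test_that("most source power lies inside the carrier band", {
  src <- synthSource(SourceModel(), "close", 2, seed = 7)
  x <- traceSamples(src)
  for (ch in 1:3)
    expect_gt(oracleBandFraction(x[, ch], sampleRate(src), 20, 450), 0.9)
})

test_that("source generation is deterministic in the seed", {
  a <- synthSource(SourceModel(), "open", 1, seed = 42)
  b <- synthSource(SourceModel(), "open", 1, seed = 42)
  c <- synthSource(SourceModel(), "open", 1, seed = 43)
  expect_identical(traceSamples(a), traceSamples(b))
  expect_false(identical(traceSamples(a), traceSamples(c)))
})

test_that("source rejects bad inputs", {
  expect_error(synthSource(SourceModel(), "close", 0, seed = 1), "positive")
  expect_error(synthSource(SourceModel(), "grip", 1, seed = 1))
})

test_that("unity electrode transfer is an exact identity and conserves power", {
  src <- synthSource(SourceModel(), "flexion", 1, seed = 3)
  out <- applyElectrode(src, ElectrodeTransfer(gainScale = 1))
  expect_identical(traceSamples(out), traceSamples(src))
  shelved <- applyElectrode(src, ElectrodeTransfer(hfTiltDb = 0), seed = 5)
  expect_equal(sum(traceSamples(shelved)^2), sum(traceSamples(src)^2))
})

test_that("a +6 dB shelf doubles a 300 Hz tone", {
  t <- (0:3199) / 1600
  tone <- MeasurementTrace(sin(2 * pi * 300 * t), fs = 1600)
  out <- traceSamples(applyElectrode(tone, ElectrodeTransfer(hfTiltDb = 6)))
  expect_equal(max(abs(out)), 2, tolerance = 0.01)
})

test_that("the PPy-like shelf raises high-band power relative to the wet view", {
  set.seed(11)
  wn <- MeasurementTrace(matrix(rnorm(3200 * 3), ncol = 3), fs = 1600)
  ppy <- applyElectrode(wn, ppyTransfer(noiseDensity = 0))
  wet <- applyElectrode(wn, wetTransfer(noiseDensity = 0))
  ratio <- function(tr) {
    x <- traceSamples(tr)
    sum(sapply(1:3, function(c) oracleBandPower(x[, c], 1600, 150.1, 800))) /
      sum(sapply(1:3, function(c) oracleBandPower(x[, c], 1600, 0, 150)))
  }
  expect_gt(ratio(ppy), ratio(wet))
})

test_that("impedance draws reproduce the per-level imbalance summaries", {
  specs <- noiseLevelSpecs()
  st1 <- drawImpedanceStates(specs[[1]], 1000, seed = 21)
  idx1 <- t(vapply(st1, imbalanceIndices, numeric(2)))
  se <- specs[[1]]@magDiffSd / sqrt(1000)
  expect_lt(abs(mean(idx1[, "magDiff"]) - 1560), 3 * se)

  st3 <- drawImpedanceStates(specs[[3]], 1000, seed = 22)
  idx3 <- t(vapply(st3, imbalanceIndices, numeric(2)))
  se3 <- specs[[3]]@phaseDiffSd / sqrt(1000)
  expect_lt(abs(mean(idx3[, "phaseDiff"]) - 33.16), 3 * se3)
})

test_that("zero-SD level specs are degenerate at the mean", {
  sp <- NoiseLevelSpec(2, magDiffMean = 5000, magDiffSd = 0,
                       phaseDiffMean = 4, phaseDiffSd = 0)
  st <- drawImpedanceStates(sp, 20, seed = 1)
  idx <- t(vapply(st, imbalanceIndices, numeric(2)))
  expect_equal(unname(idx[, "magDiff"]), rep(5000, 20))
  expect_equal(unname(idx[, "phaseDiff"]), rep(4, 20))
})

test_that("widening the envelope separation of two motions raises their accuracy", {
  # Three settings of the close/open envelope separation; everything else is
  # the clean default chain (no front-end noise) to isolate the knob.
  accs <- vapply(c(0.15, 0.5, 1), function(alpha) {
    base <- c(1.0, 0.4, 0.2) * 1e-3
    delta <- c(0.2, 1.0, 0.4) * 1e-3 - base
    env <- SourceModel()@envelope
    env["open", ] <- base + alpha * delta
    model <- SourceModel(envelope = env)
    cfg <- EpochConfig(); spec <- FeatureSpec()
    feats <- list(); labs <- character(0)
    for (m in motionLabels()) {
      tr <- synthSource(model, m, 1.5, seed = 600 + match(m, motionLabels()))
      f <- traceFeatures(tr, spec, cfg)
      feats[[m]] <- f; labs <- c(labs, rep(m, nrow(f)))
    }
    x <- do.call(rbind, feats)
    ann <- trainAnn(x, labs, AnnModel(epochs = 300, seed = 5))
    test <- lapply(c("close", "open"), function(m)
      traceFeatures(synthSource(model, m, 1, seed = 700 + match(m, motionLabels())),
                    spec, cfg))
    pred <- c(as.character(classifyFeatures(ann, test[[1]])),
              as.character(classifyFeatures(ann, test[[2]])))
    truth <- c(rep("close", nrow(test[[1]])), rep("open", nrow(test[[2]])))
    mean(pred == truth)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})
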