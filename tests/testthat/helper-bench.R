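# Shared helpers: small deterministic objects and brute-force oracles used
# across the test files. Oracles are written in plain arithmetic, independent
# of the implementation paths they check.

# Direct periodogram power of a vector in [lo, hi] Hz (brute-force DFT sum).
oracleBandPower <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (0:(n - 1)) * fs / n
  fold <- pmin(f, fs - f)
  sum(p[fold >= lo & fold <= hi])
}

# Fraction of total power inside [lo, hi] Hz.
oracleBandFraction <- function(x, fs, lo, hi) {
  oracleBandPower(x, fs, lo, hi) / (sum(Mod(fft(x))^2) / length(x))
}

# Plain run-length scan for runs of >= minRun TRUEs.
oracleRunMask <- function(hot, minRun) {
  n <- length(hot)
  mask <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (hot[i]) {
      j <- i
      while (j < n && hot[j + 1]) j <- j + 1
      if (j - i + 1 >= minRun) mask[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  mask
}

# A bench configuration small enough for fast end-to-end tests.
smallBenchConfig <- function() {
  defaultExperimentConfig(trainSecondsPerClass = 1, testSecondsPerClass = 1,
                          annEpochs = 200L)
}

# Labeled level-1 front-end feature sets for classifier tests: one matrix of
# epoch features per motion, generated through the full default chain.
benchFeatureSet <- function(secondsPerClass, seed,
                            cfg = defaultExperimentConfig()) {
  states <- drawImpedanceStates(cfg$noiseLevels[[1]], 5, seed = seed)
  feats <- list(); labs <- character(0)
  for (i in seq_along(motionLabels())) {
    m <- motionLabels()[i]
    src <- synthSource(cfg$source, m, secondsPerClass, seed = seed + 13 * i)
    view <- applyElectrode(src, cfg$ppy, seed = seed + 131 * i)
    tr <- simulateMeasurement(view, cfg$interference, states[[i]],
                              cfg$amplifier, cfg$filter)
    f <- traceFeatures(tr, cfg$features, cfg$epoch)
    feats[[m]] <- f
    labs <- c(labs, rep(m, nrow(f)))
  }
  list(x = do.call(rbind, feats), y = labs)
}
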