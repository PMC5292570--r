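## Internal numerical helpers.

dbToGain <- function(db) 10^(db / 20)

clipToRails <- function(x, rail) pmin(pmax(x, -rail), rail)

## Round half away from zero to `digits` decimals (presentation-time rounding
## convention used when comparing against printed reference values).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Moments of a normal(mu, sigma) truncated to [0, Inf).
truncNormMoments <- function(mu, sigma) {
  a <- -mu / sigma
  lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

## Parent (mu, sigma) such that the [0, Inf)-truncated normal has the target
## mean and SD (moment matching; plain truncation would bias the sample mean
## upward whenever sd is comparable to the mean).
truncNormParams <- function(targetMean, targetSd) {
  if (targetSd == 0) return(c(mu = targetMean, sigma = 0))
  obj <- function(p) {
    m <- truncNormMoments(p[1], exp(p[2]))
    (m[["mean"]] / targetMean - 1)^2 + (m[["sd"]] / targetSd - 1)^2
  }
  fit <- stats::optim(c(targetMean, log(targetSd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

## Draw n values from the moment-matched zero-truncated normal.
rTruncNorm <- function(n, targetMean, targetSd) {
  if (targetSd == 0) return(rep(targetMean, n))
  p <- truncNormParams(targetMean, targetSd)
  lo <- stats::pnorm(0, p[["mu"]], p[["sigma"]])
  stats::qnorm(stats::runif(n, lo, 1), p[["mu"]], p[["sigma"]])
}

## Deterministic fan-out of one experiment seed into per-stage child seeds
## (kept below 2^31 - 1).
childSeed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %% 2147483647
}

## Rolling polynomial hash of an R object's serialization, hex string.
## Used to stamp reports with a configuration fingerprint.
fnvHash <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## One-sided periodogram power of a vector: |DFT|^2 / n per bin, bins
## 0 .. floor(n/2). Shared by features and band-power summaries.
halfSpectrumPower <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  (Mod(X)^2 / n)[seq_len(floor(n / 2) + 1)]
}

## Frequencies (Hz) of the one-sided bins for length n at rate fs.
halfSpectrumFreqs <- function(n, fs) (0:floor(n / 2)) * fs / n

## Moving average with half-width h and shrinking (partial) windows at the
## edges, so no bin is lost.
movingAverage <- function(x, h) {
  if (h == 0) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
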