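#' Generate a synthetic multi-channel sEMG source
#'
#' Draws band-pass-filtered Gaussian white noise per channel (the EMG-shaped
#' stochastic carrier), normalizes each carrier to unit RMS, and scales it by
#' the model's per-motion activation amplitude with a raised-cosine onset
#' ramp. After the onset transient each channel's RMS equals the configured
#' amplitude for the requested motion, and essentially all signal power lies
#' inside the carrier band.
#'
#' @param model A [SourceModel].
#' @param motion One of [motionLabels()].
#' @param durationS Duration in seconds (> 0).
#' @param seed Integer seed; the same seed and parameters give a bit-identical
#'   trace.
#' @return A [MeasurementTrace] of \code{model@nChannels} channels.
#' @examples
#' src <- synthSource(SourceModel(), "close", 1, seed = 7)
#' apply(traceSamples(src), 2, function(v) sqrt(mean(v^2)))
#' @export
synthSource <- function(model, motion, durationS, seed) {
  stopifnot(is(model, "SourceModel"))
  if (durationS <= 0) stop("durationS must be positive")
  motion <- match.arg(motion, motionLabels())
  n <- round(model@fs * durationS)
  amps <- model@envelope[motion, ]

  bf <- signal::butter(4, model@carrierBand / (model@fs / 2), type = "pass")
  riseN <- round(model@envelopeRiseMs * model@fs / 1000)
  ramp <- rep(1, n)
  if (riseN > 0) {
    k <- seq_len(min(riseN, n))
    ramp[k] <- 0.5 * (1 - cos(pi * (k - 1) / riseN))
  }

  set.seed(as.integer(seed %% 2147483647))
  samples <- vapply(seq_len(model@nChannels), function(ch) {
    w <- stats::rnorm(n)
    carrier <- signal::filtfilt(bf, w)
    carrier <- carrier / sqrt(mean(carrier^2))
    amps[ch] * ramp * carrier
  }, numeric(n))
  MeasurementTrace(samples, fs = model@fs)
}

#' Apply an electrode transfer to a trace
#'
#' Models the electrode as a broadband gain plus a zero-phase high-frequency
#' shelf realized in the frequency domain (all DFT components above the pivot
#' frequency scaled by \code{10^(hfTiltDb/20)}), plus additive white
#' measurement noise. With zero tilt and zero noise the output is exactly
#' \code{gainScale} times the input.
#'
#' @param trace A [MeasurementTrace].
#' @param transfer An [ElectrodeTransfer].
#' @param seed Integer seed for the additive noise (ignored when
#'   \code{noiseDensity} is 0).
#' @return A [MeasurementTrace] of the same length.
#' @export
applyElectrode <- function(trace, transfer, seed = 1) {
  stopifnot(is(trace, "MeasurementTrace"), is(transfer, "ElectrodeTransfer"))
  x <- traceSamples(trace)
  n <- nrow(x)
  if (n == 0) stop("empty trace")
  fs <- sampleRate(trace)
  if (transfer@hfPivotHz >= fs / 2)
    stop("hfPivotHz must lie below the Nyquist frequency")

  out <- x * transfer@gainScale
  if (transfer@hfTiltDb != 0) {
    freqs <- (0:(n - 1)) * fs / n
    fold <- pmin(freqs, fs - freqs)          # analog frequency of each DFT bin
    shelf <- ifelse(fold > transfer@hfPivotHz, dbToGain(transfer@hfTiltDb), 1)
    out <- apply(out, 2, function(v) Re(stats::fft(stats::fft(v) * shelf,
                                                   inverse = TRUE)) / n)
  }
  if (transfer@noiseDensity > 0) {
    set.seed(as.integer(seed %% 2147483647))
    sdNoise <- transfer@noiseDensity * sqrt(fs / 2)
    out <- out + matrix(stats::rnorm(length(out), sd = sdNoise), nrow = n)
  }
  MeasurementTrace(out, fs = fs, channelIds = channelIds(trace),
                   excluded = excludedMask(trace))
}

#' Draw impedance states at a rest-state noise level
#'
#' Samples magnitude and phase imbalances from zero-truncated normal
#' distributions moment-matched to the level's mean/SD, and splits each
#' difference symmetrically around a baseline impedance (default 50 kOhm at
#' -20 degrees): the two arms get \code{baselineMag -/+ magDiff/2} and
#' \code{baselinePhase -/+ phaseDiff/2}. The trimmer resistances are left at
#' zero, so [imbalanceIndices()] of a drawn state returns exactly the drawn
#' differences; over many draws their sample means match the level's means.
#'
#' @param spec A [NoiseLevelSpec].
#' @param n Number of states to draw.
#' @param seed Integer seed.
#' @param baselineMag Baseline impedance magnitude in ohm.
#' @param baselinePhase Baseline impedance phase in degrees.
#' @return A list of \code{n} [ImpedanceState] objects.
#' @examples
#' states <- drawImpedanceStates(noiseLevelSpecs()[[1]], 5, seed = 1)
#' imbalanceIndices(states[[1]])
#' @export
drawImpedanceStates <- function(spec, n, seed, baselineMag = 5e4,
                                baselinePhase = -20) {
  stopifnot(is(spec, "NoiseLevelSpec"))
  set.seed(as.integer(seed %% 2147483647))
  magDiff <- rTruncNorm(n, spec@magDiffMean, spec@magDiffSd)
  phaseDiff <- rTruncNorm(n, spec@phaseDiffMean, spec@phaseDiffSd)
  magDiff <- pmin(magDiff, 1.96 * baselineMag)   # keep both arms positive
  lapply(seq_len(n), function(i) {
    ImpedanceState(z1Mag = baselineMag - magDiff[i] / 2,
                   z1Phase = baselinePhase - phaseDiff[i] / 2,
                   z2Mag = baselineMag + magDiff[i] / 2,
                   z2Phase = baselinePhase + phaseDiff[i] / 2)
  })
}
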