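## Measurement-electronics simulation: impedance-driven common-mode coupling,
## interference injection, amplification, filtering, saturation, and the
## switched impedance-measurement protocol.

## Complex source impedance of each arm including its series trimmer.
armImpedances <- function(state) {
  z1 <- complex(modulus = state@z1Mag, argument = state@z1Phase * pi / 180) + state@r1
  z2 <- complex(modulus = state@z2Mag, argument = state@z2Phase * pi / 180) + state@r2
  list(z1 = z1, z2 = z2)
}

#' Source-impedance imbalance indices
#'
#' The two imbalance indices tabulated per noise level: the absolute
#' difference of the arm impedance magnitudes and the absolute difference of
#' their phase angles (in degrees), each arm taken as \code{Z + R} with its
#' series trimmer. Note this is the difference of magnitudes,
#' \code{| |Z1+R1| - |Z2+R2| |}, not the magnitude of the complex difference;
#' the coupling model ([commonModeCoupling()]) uses the full complex
#' difference.
#'
#' @param state An [ImpedanceState].
#' @return Named numeric \code{c(magDiff = , phaseDiff = )} in ohm / degrees.
#' @export
setMethod("imbalanceIndices", "ImpedanceState", function(state) {
  z <- armImpedances(state)
  c(magDiff = abs(Mod(z$z1) - Mod(z$z2)),
    phaseDiff = abs(Arg(z$z1) - Arg(z$z2)) * 180 / pi)
})

#' Common-mode to differential conversion gain
#'
#' The textbook potential-divider model of CMRR degradation by source
#' impedance imbalance: each arm divides the common-mode voltage through its
#' source impedance against the amplifier's common-mode input impedance, so
#' the differential error gain is
#' \deqn{g = Z_{in}\left(\frac{1}{Z_{in}+Z_1'} - \frac{1}{Z_{in}+Z_2'}\right)
#'   + 10^{-CMRR/20}}
#' with \eqn{Z_k' = Z_k + R_k}, plus the amplifier's intrinsic common-mode
#' leakage. For fixed \eqn{Z_{in}}, \eqn{|g|} grows with the complex arm
#' difference \eqn{|Z_2' - Z_1'|}.
#'
#' @param state An [ImpedanceState].
#' @param amp An [AmplifierSpec].
#' @return A complex scalar gain.
#' @export
commonModeCoupling <- function(state, amp) {
  stopifnot(is(state, "ImpedanceState"), is(amp, "AmplifierSpec"))
  zin <- amp@inputImpedance
  if (Mod(zin) == 0) stop("degenerate input impedance")
  z <- armImpedances(state)
  leak <- if (is.infinite(amp@intrinsicCmrrDb)) 0 else 10^(-amp@intrinsicCmrrDb / 20)
  zin * (1 / (zin + z$z1) - 1 / (zin + z$z2)) + leak
}

## Mains-harmonic common-mode waveform (volts at the body), meter tone
## excluded (handled by applyMeterSchedule). `phase` shifts every component,
## used to apply the argument of the complex coupling gain.
mainsWaveform <- function(interference, n, fs, phase = 0) {
  t <- (0:(n - 1)) / fs
  v <- numeric(n)
  for (f in names(interference@harmonicAmplitudes)) {
    a <- interference@harmonicAmplitudes[[f]]
    if (a > 0) v <- v + a * sin(2 * pi * as.numeric(f) * t + phase)
  }
  v
}

## Zero-phase band-pass (or high-pass when the upper edge is at/above
## Nyquist) + notch chain.
applyFilterChain <- function(x, filt) {
  ny <- filt@fs / 2
  if (filt@bandpass[2] >= ny) {
    bf <- signal::butter(filt@order, filt@bandpass[1] / ny, type = "high")
  } else {
    bf <- signal::butter(filt@order, filt@bandpass / ny, type = "pass")
  }
  y <- signal::filtfilt(bf, x)
  w0 <- 2 * pi * filt@notchHz / filt@fs
  alpha <- sin(w0) / (2 * filt@notchQ)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::filtfilt(signal::Arma(b = b, a = a), y)
}

#' Simulate the differential measurement chain
#'
#' Runs a differential source through the full front end: the common-mode
#' interference is converted to a differential error through the coupling
#' gain of the impedance state, the sum is amplified by the preamplifier,
#' band-pass and notch filtered, amplified by the second stage, and clipped
#' to the output rails:
#' \code{clip( G2 * notch( bandpass( G1 * (v_diff + g * v_cm) ) ) )}.
#'
#' @param diffSource A [MeasurementTrace] of the differential source (volts at
#'   the amplifier input).
#' @param interference An [InterferenceModel] (mains harmonics; the meter tone
#'   is injected separately by [applyMeterSchedule()]).
#' @param state An [ImpedanceState].
#' @param amp An [AmplifierSpec].
#' @param filt A [FilterChainSpec]; must share \code{fs} with the source.
#' @return A [MeasurementTrace] of amplifier output volts, all samples within
#'   the rails.
#' @export
simulateMeasurement <- function(diffSource, interference, state, amp, filt) {
  stopifnot(is(diffSource, "MeasurementTrace"))
  fs <- sampleRate(diffSource)
  if (abs(filt@fs - fs) > 1e-9) stop("sampling-rate mismatch between source and filter chain")
  x <- traceSamples(diffSource)
  n <- nrow(x)
  g <- commonModeCoupling(state, amp)
  cm <- Mod(g) * mainsWaveform(interference, n, fs, phase = Arg(g))
  g1 <- dbToGain(amp@preGainDb)
  g2 <- dbToGain(amp@secondGainDb)
  out <- apply(x, 2, function(v) {
    clipToRails(g2 * applyFilterChain(g1 * (v + cm), filt), amp@railV)
  })
  MeasurementTrace(matrix(out, nrow = n), fs = fs,
                   channelIds = channelIds(diffSource),
                   excluded = excludedMask(diffSource))
}

#' Inject the impedance-meter tone and mark its intervals excluded
#'
#' During each interval of the meter schedule the 1 Vrms 300 Hz measurement
#' tone reaches the amplifier input; amplified by 40 dB it exceeds the rails
#' by an order of magnitude, so the output saturates into a clipped square
#' wave for the whole interval. The exclusion mask is set on the intervals
#' plus a settling margin on each side; downstream analyses skip those
#' samples, mirroring the exclusion of the meter output from signal analysis.
#'
#' @param trace A [MeasurementTrace] of amplifier output.
#' @param interference An [InterferenceModel] carrying the meter schedule.
#' @param amp The [AmplifierSpec] of the chain that produced \code{trace}.
#' @param settlingMarginS Extra exclusion margin in seconds on each side.
#' @return The modified [MeasurementTrace].
#' @export
applyMeterSchedule <- function(trace, interference, amp, settlingMarginS = 0.05) {
  stopifnot(is(trace, "MeasurementTrace"))
  sch <- interference@meterSchedule
  if (nrow(sch) == 0) return(trace)
  fs <- sampleRate(trace)
  n <- nSamples(trace)
  if (any(sch < 0) || any(sch > n / fs)) stop("meter schedule outside the trace")
  x <- traceSamples(trace)
  mask <- excludedMask(trace)
  gain <- dbToGain(amp@preGainDb) * dbToGain(amp@secondGainDb)
  t <- (0:(n - 1)) / fs
  for (i in seq_len(nrow(sch))) {
    on <- which(t >= sch[i, 1] & t < sch[i, 2])
    tone <- sqrt(2) * interference@meterToneV *
      sin(2 * pi * interference@meterToneHz * t[on])
    x[on, ] <- clipToRails(gain * tone, amp@railV)
    lo <- max(1, min(on) - round(settlingMarginS * fs))
    hi <- min(n, max(on) + round(settlingMarginS * fs))
    mask[lo:hi] <- TRUE
  }
  MeasurementTrace(x, fs = fs, channelIds = channelIds(trace), excluded = mask)
}

#' Mark saturated runs as excluded
#'
#' Scans every channel for runs of at least \code{minRun} consecutive samples
#' with \code{|v| >= thresholdV} and sets the exclusion mask on those runs
#' (any channel saturating excludes the sample for all channels, since the
#' epoch-level analyses act on all channels jointly).
#'
#' @param trace A [MeasurementTrace].
#' @param thresholdV Saturation threshold in volts.
#' @param minRun Minimum run length in samples.
#' @return The trace with an updated exclusion mask.
#' @export
excludeSaturated <- function(trace, thresholdV, minRun = 8L) {
  stopifnot(is(trace, "MeasurementTrace"))
  x <- traceSamples(trace)
  hot <- apply(abs(x) >= thresholdV, 1, any)
  mask <- excludedMask(trace)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values & r$lengths >= minRun)) mask[starts[j]:ends[j]] <- TRUE
  MeasurementTrace(x, fs = sampleRate(trace), channelIds = channelIds(trace),
                   excluded = mask)
}
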