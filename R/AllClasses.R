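#' Motion classes of the myoelectric control task
#'
#' The five control classes used throughout the package. \code{"relax"} is the
#' designated rest class: its source activation is near zero by construction.
#'
#' @return Character vector of the five class names, in canonical order.
#' @export
#' @examples
#' motionLabels()
motionLabels <- function() c("relax", "close", "open", "flexion", "extension")

.MOTIONS <- c("relax", "close", "open", "flexion", "extension")

## ---------------------------------------------------------------------------
## Source / electrode side
## ---------------------------------------------------------------------------

#' @rdname SourceModel
#' @export
setClass("SourceModel",
  representation(
    nChannels = "integer",
    fs = "numeric",
    carrierBand = "numeric",
    envelope = "matrix",
    envelopeRiseMs = "numeric"
  )
)

setValidity("SourceModel", function(object) {
  msg <- NULL
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(object@carrierBand) != 2L ||
      object@carrierBand[1] <= 0 ||
      object@carrierBand[2] <= object@carrierBand[1] ||
      object@carrierBand[2] >= object@fs / 2)
    msg <- c(msg, "carrierBand must be (low, high) within (0, fs/2)")
  env <- object@envelope
  if (!identical(rownames(env), .MOTIONS))
    msg <- c(msg, "envelope rows must be the five motion labels, in order")
  if (ncol(env) != object@nChannels)
    msg <- c(msg, "envelope must have one column per channel")
  if (any(env < 0)) msg <- c(msg, "activation amplitudes must be >= 0")
  active <- env[setdiff(.MOTIONS, "relax"), , drop = FALSE]
  if (max(env["relax", ]) > 0.05 * max(active))
    msg <- c(msg, "relax activation must be <= 5% of the maximum active-class activation")
  if (object@envelopeRiseMs < 0) msg <- c(msg, "envelopeRiseMs must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Stochastic multi-channel sEMG source model
#'
#' Describes the synthetic muscle-source generator: an EMG-shaped stochastic
#' carrier (band-pass-filtered Gaussian noise, default 20--450 Hz) whose
#' per-channel RMS amplitude is set by a motion-class envelope matrix with a
#' smoothed onset. Amplitudes are volts RMS at the skin; surface EMG is below
#' 1 mV, so the default active classes peak at 1e-3 V and the rest class sits
#' two orders of magnitude lower.
#'
#' @param nChannels Number of differential channels (default 3).
#' @param fs Sampling rate in Hz (default 1600).
#' @param carrierBand Numeric length-2, carrier band edges in Hz.
#' @param envelope 5 x \code{nChannels} matrix of per-class, per-channel RMS
#'   amplitudes in volts; rows must be \code{motionLabels()}. The default gives
#'   each active motion a distinct dominant channel and a near-zero rest class,
#'   so the five classes are separable by design.
#' @param envelopeRiseMs Raised-cosine onset ramp duration in ms.
#' @return A \code{SourceModel} object.
#' @seealso [synthSource()]
#' @export
SourceModel <- function(nChannels = 3L, fs = 1600, carrierBand = c(20, 450),
                        envelope = NULL, envelopeRiseMs = 100) {
  nChannels <- as.integer(nChannels)
  if (is.null(envelope)) {
    envelope <- 1e-3 * rbind(
      relax     = rep(0.01, nChannels),
      close     = c(1.0, 0.4, 0.2)[seq_len(nChannels)],
      open      = c(0.2, 1.0, 0.4)[seq_len(nChannels)],
      flexion   = c(0.4, 0.2, 1.0)[seq_len(nChannels)],
      extension = c(0.7, 0.7, 0.1)[seq_len(nChannels)]
    )
  }
  new("SourceModel", nChannels = nChannels, fs = fs,
      carrierBand = as.numeric(carrierBand), envelope = envelope,
      envelopeRiseMs = envelopeRiseMs)
}

#' @rdname ElectrodeTransfer
#' @export
setClass("ElectrodeTransfer",
  representation(
    gainScale = "numeric",
    hfTiltDb = "numeric",
    hfPivotHz = "numeric",
    noiseDensity = "numeric"
  )
)

setValidity("ElectrodeTransfer", function(object) {
  msg <- NULL
  if (object@gainScale <= 0) msg <- c(msg, "gainScale must be > 0")
  if (object@hfPivotHz <= 0) msg <- c(msg, "hfPivotHz must be > 0")
  if (object@noiseDensity < 0) msg <- c(msg, "noiseDensity must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Electrode transfer descriptions
#'
#' A linear electrode model: a broadband gain, a zero-phase high-frequency
#' shelf (applied above a pivot frequency, default 150 Hz), and additive white
#' measurement noise. \code{wetTransfer()} and \code{ppyTransfer()} give the
#' package defaults for gelled Ag/AgCl ("wet") electrodes and dry
#' polypyrrole-coated fabric ("PPy") electrodes: the wet view is slightly
#' larger in amplitude, while the PPy view carries relatively more power above
#' the pivot. Published comparisons report these differences only
#' qualitatively, so the default magnitudes are configuration, not claims.
#'
#' @param gainScale Unitless broadband multiplier.
#' @param hfTiltDb Relative gain in dB applied above \code{hfPivotHz}.
#' @param hfPivotHz Shelf pivot frequency in Hz.
#' @param noiseDensity Additive white noise RMS per sqrt(Hz), in V/sqrt(Hz).
#' @return An \code{ElectrodeTransfer} object.
#' @seealso [applyElectrode()]
#' @export
ElectrodeTransfer <- function(gainScale = 1, hfTiltDb = 0, hfPivotHz = 150,
                              noiseDensity = 0) {
  new("ElectrodeTransfer", gainScale = gainScale, hfTiltDb = hfTiltDb,
      hfPivotHz = hfPivotHz, noiseDensity = noiseDensity)
}

#' @rdname ElectrodeTransfer
#' @export
wetTransfer <- function(noiseDensity = 2e-7) {
  ElectrodeTransfer(gainScale = 1.1, hfTiltDb = 0, noiseDensity = noiseDensity)
}

#' @rdname ElectrodeTransfer
#' @export
ppyTransfer <- function(noiseDensity = 2e-7) {
  ElectrodeTransfer(gainScale = 1.0, hfTiltDb = 3, hfPivotHz = 150,
                    noiseDensity = noiseDensity)
}

## ---------------------------------------------------------------------------
## Impedance side
## ---------------------------------------------------------------------------

#' @rdname ImpedanceState
#' @export
setClass("ImpedanceState",
  representation(
    z1Mag = "numeric", z1Phase = "numeric",
    z2Mag = "numeric", z2Phase = "numeric",
    r1 = "numeric", r2 = "numeric"
  )
)

setValidity("ImpedanceState", function(object) {
  msg <- NULL
  if (object@z1Mag <= 0 || object@z2Mag <= 0)
    msg <- c(msg, "impedance magnitudes must be > 0")
  if (object@r1 < 0 || object@r1 > 2e5 || object@r2 < 0 || object@r2 > 2e5)
    msg <- c(msg, "r1, r2 must lie in [0, 200000] ohm (0-200 kOhm trimmers)")
  if (is.null(msg)) TRUE else msg
})

#' Complex source-impedance state of the two amplifier inputs
#'
#' The source impedance seen by each input of the differential amplifier:
#' tissue + skin-electrode + electrode impedance, represented by its magnitude
#' and phase measured at 300 Hz, plus a series trimmer resistance (0--200 kOhm)
#' on each arm. The imbalance between the two arms drives common-mode to
#' differential conversion (see [commonModeCoupling()]).
#'
#' @param z1Mag,z2Mag Impedance magnitudes in ohm.
#' @param z1Phase,z2Phase Impedance phase angles in degrees.
#' @param r1,r2 Series trimmer resistances in ohm.
#' @return An \code{ImpedanceState} object.
#' @export
ImpedanceState <- function(z1Mag, z1Phase, z2Mag, z2Phase, r1 = 0, r2 = 0) {
  new("ImpedanceState", z1Mag = z1Mag, z1Phase = z1Phase,
      z2Mag = z2Mag, z2Phase = z2Phase, r1 = r1, r2 = r2)
}

#' @rdname NoiseLevelSpec
#' @export
setClass("NoiseLevelSpec",
  representation(
    level = "integer",
    magDiffMean = "numeric", magDiffSd = "numeric",
    phaseDiffMean = "numeric", phaseDiffSd = "numeric"
  )
)

setValidity("NoiseLevelSpec", function(object) {
  msg <- NULL
  if (!object@level %in% 1:3) msg <- c(msg, "level must be 1, 2 or 3")
  if (object@magDiffMean < 0 || object@phaseDiffMean < 0)
    msg <- c(msg, "imbalance means must be >= 0")
  if (object@magDiffSd < 0 || object@phaseDiffSd < 0)
    msg <- c(msg, "imbalance SDs must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Impedance-imbalance distribution of a rest-state noise level
#'
#' Mean and SD of the magnitude (ohm) and phase-angle (degree) differences
#' between the two source impedances at one of the three rest-state noise
#' levels. \code{noiseLevelSpecs()} returns the three levels calibrated to the
#' published per-level summaries (magnitude means 1560 / 7880 / 21250 ohm,
#' phase means 1.14 / 8.92 / 33.16 degrees, with their SDs), computed from the
#' packaged impedance reference table.
#'
#' @param level Noise level, 1 (little noise), 2 (noise within +/- 6 V) or
#'   3 (noise reaching the +/- 9 V rails).
#' @param magDiffMean,magDiffSd Magnitude-difference mean and SD in ohm.
#' @param phaseDiffMean,phaseDiffSd Phase-difference mean and SD in degrees.
#' @return A \code{NoiseLevelSpec}; \code{noiseLevelSpecs()} a list of three.
#' @seealso [drawImpedanceStates()], [referenceTable()]
#' @export
NoiseLevelSpec <- function(level, magDiffMean, magDiffSd,
                           phaseDiffMean, phaseDiffSd) {
  new("NoiseLevelSpec", level = as.integer(level),
      magDiffMean = magDiffMean, magDiffSd = magDiffSd,
      phaseDiffMean = phaseDiffMean, phaseDiffSd = phaseDiffSd)
}

#' @rdname NoiseLevelSpec
#' @export
noiseLevelSpecs <- function() {
  tab <- referenceTable("impedance")
  lapply(1:3, function(lv) {
    d <- tab[tab$level == lv, ]
    NoiseLevelSpec(level = lv,
                   magDiffMean = mean(d$mag_ohm), magDiffSd = stats::sd(d$mag_ohm),
                   phaseDiffMean = mean(d$phase_deg), phaseDiffSd = stats::sd(d$phase_deg))
  })
}

## ---------------------------------------------------------------------------
## Front-end electronics
## ---------------------------------------------------------------------------

#' @rdname AmplifierSpec
#' @export
setClass("AmplifierSpec",
  representation(
    preGainDb = "numeric",
    secondGainDb = "numeric",
    inputImpedance = "complex",
    intrinsicCmrrDb = "numeric",
    railV = "numeric"
  )
)

setValidity("AmplifierSpec", function(object) {
  msg <- NULL
  if (object@preGainDb <= 0) msg <- c(msg, "preGainDb must be > 0")
  if (object@railV <= 0) msg <- c(msg, "railV must be > 0")
  if (Mod(object@inputImpedance) <= 0) msg <- c(msg, "input impedance must be non-zero")
  if (is.null(msg)) TRUE else msg
})

#' Differential amplifier chain description
#'
#' An instrumentation-amplifier front end: a 40 dB preamplifier, a second gain
#' stage, a finite common-mode input impedance, an intrinsic common-mode
#' rejection ratio, and +/- 9 V output rails at which the output clips. The
#' second-stage default (26 dB, total gain x2000) puts the ~3-sigma peak of a
#' 1 mV RMS source at about two thirds of the rails. \code{benchAmplifier()}
#' is the amplifier used by the default simulation bench; it raises the
#' intrinsic CMRR to 120 dB, typical of an instrumentation amplifier at
#' gain 100, so that the imbalance-driven coupling, not the amplifier floor,
#' dominates the rest-state noise.
#'
#' @param preGainDb Preamplifier gain in dB (default 40).
#' @param secondGainDb Second-stage gain in dB (default 26).
#' @param inputImpedance Common-mode input impedance in ohm (complex allowed).
#' @param intrinsicCmrrDb Intrinsic CMRR in dB (may be \code{Inf}).
#' @param railV Output rail magnitude in volts (default 9).
#' @return An \code{AmplifierSpec} object.
#' @export
AmplifierSpec <- function(preGainDb = 40, secondGainDb = 26,
                          inputImpedance = complex(real = 1e9),
                          intrinsicCmrrDb = 100, railV = 9) {
  new("AmplifierSpec", preGainDb = preGainDb, secondGainDb = secondGainDb,
      inputImpedance = as.complex(inputImpedance),
      intrinsicCmrrDb = intrinsicCmrrDb, railV = railV)
}

#' @rdname AmplifierSpec
#' @export
benchAmplifier <- function() AmplifierSpec(intrinsicCmrrDb = 120)

#' @rdname FilterChainSpec
#' @export
setClass("FilterChainSpec",
  representation(
    bandpass = "numeric",
    order = "integer",
    notchHz = "numeric",
    notchQ = "numeric",
    fs = "numeric"
  )
)

setValidity("FilterChainSpec", function(object) {
  msg <- NULL
  if (length(object@bandpass) != 2L || object@bandpass[1] <= 0 ||
      object@bandpass[2] <= object@bandpass[1])
    msg <- c(msg, "bandpass must be increasing (low, high), low > 0")
  if (object@bandpass[1] >= object@fs / 2)
    msg <- c(msg, "bandpass low edge must be below Nyquist")
  if (object@notchHz <= object@bandpass[1] || object@notchHz >= object@fs / 2)
    msg <- c(msg, "notch must lie inside the passband and below Nyquist")
  if (object@notchQ <= 0) msg <- c(msg, "notchQ must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Band-pass + notch filter chain
#'
#' The analog filter block of the measurement circuit: a 1--1000 Hz band-pass
#' and a 50 Hz mains notch. Filters are realized as Butterworth sections plus
#' an RBJ biquad notch, applied forward-backward for zero phase. A band edge
#' at or above the Nyquist frequency of \code{fs} (the 1000 Hz edge at
#' fs = 1600 Hz) corresponds to an analog pole above the sampled band and is
#' skipped; only the high-pass half and the notch then act.
#'
#' @param bandpass Numeric length-2 band edges in Hz (default \code{c(1, 1000)}).
#' @param order Butterworth order per edge (default 2).
#' @param notchHz Notch center frequency in Hz (default 50).
#' @param notchQ Notch quality factor (default 30).
#' @param fs Sampling rate in Hz.
#' @return A \code{FilterChainSpec} object.
#' @export
FilterChainSpec <- function(bandpass = c(1, 1000), order = 2L, notchHz = 50,
                            notchQ = 30, fs = 1600) {
  new("FilterChainSpec", bandpass = as.numeric(bandpass),
      order = as.integer(order), notchHz = notchHz, notchQ = notchQ, fs = fs)
}

#' @rdname InterferenceModel
#' @export
setClass("InterferenceModel",
  representation(
    mainsHz = "numeric",
    harmonicAmplitudes = "numeric",
    meterToneHz = "numeric",
    meterToneV = "numeric",
    meterSchedule = "matrix"
  )
)

setValidity("InterferenceModel", function(object) {
  msg <- NULL
  if (any(object@harmonicAmplitudes < 0))
    msg <- c(msg, "harmonic amplitudes must be >= 0")
  if (is.null(names(object@harmonicAmplitudes)))
    msg <- c(msg, "harmonicAmplitudes must be named by frequency in Hz")
  if (object@meterToneV < 0) msg <- c(msg, "meterToneV must be >= 0")
  sch <- object@meterSchedule
  if (nrow(sch) > 0) {
    if (ncol(sch) != 2L || any(sch[, 2] <= sch[, 1]))
      msg <- c(msg, "meterSchedule rows must be (start_s, end_s) with end > start")
    if (nrow(sch) > 1) {
      o <- order(sch[, 1])
      if (any(sch[o, 1][-1] < sch[o, 2][-nrow(sch)]))
        msg <- c(msg, "meterSchedule intervals must be disjoint")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Common-mode interference model
#'
#' Mains interference at 50 Hz and its harmonics, plus the 300 Hz 1 Vrms tone
#' injected by the LCR meter while it measures a source impedance. Harmonic
#' amplitudes are common-mode volts at the body. The default amplitudes are
#' calibrated so that, through the default amplifier and the mean per-level
#' impedance imbalances, the rest-state output lands in the three defined
#' noise bands (below ~1 V; within +/- 6 V; reaching the +/- 9 V rails); most
#' amplitude sits in the harmonics because the 50 Hz fundamental is removed by
#' the notch filter, matching the observed dominance of the 100/200/300 Hz
#' lines in rest-state spectra.
#'
#' @param mainsHz Mains fundamental in Hz (default 50).
#' @param harmonicAmplitudes Named numeric, common-mode amplitude in volts per
#'   harmonic frequency.
#' @param meterToneHz LCR meter measurement frequency in Hz (default 300).
#' @param meterToneV Meter tone level in volts RMS (default 1).
#' @param meterSchedule Two-column matrix of (start_s, end_s) on-intervals.
#' @return An \code{InterferenceModel} object.
#' @export
InterferenceModel <- function(mainsHz = 50,
                              harmonicAmplitudes = c("50" = 50, "100" = 60,
                                                     "150" = 20, "200" = 30,
                                                     "250" = 15, "300" = 30),
                              meterToneHz = 300, meterToneV = 1,
                              meterSchedule = matrix(numeric(0), ncol = 2)) {
  new("InterferenceModel", mainsHz = mainsHz,
      harmonicAmplitudes = harmonicAmplitudes, meterToneHz = meterToneHz,
      meterToneV = meterToneV, meterSchedule = meterSchedule)
}

#' @rdname InterferenceModel
#' @export
silentInterference <- function() {
  InterferenceModel(harmonicAmplitudes = c("50" = 0, "100" = 0, "150" = 0,
                                           "200" = 0, "250" = 0, "300" = 0),
                    meterToneV = 0)
}

## ---------------------------------------------------------------------------
## Measurement trace
## ---------------------------------------------------------------------------

#' @rdname MeasurementTrace
#' @export
setClass("MeasurementTrace",
  representation(
    samples = "matrix",
    fs = "numeric",
    channelIds = "character",
    excluded = "logical"
  )
)

setValidity("MeasurementTrace", function(object) {
  msg <- NULL
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(object@channelIds) != ncol(object@samples))
    msg <- c(msg, "one channel id per column required")
  if (length(object@excluded) != nrow(object@samples))
    msg <- c(msg, "excluded mask must have one entry per sample")
  if (is.null(msg)) TRUE else msg
})

#' Sampled multi-channel voltage trace
#'
#' The package's central container: a samples-by-channels voltage matrix with
#' its sampling rate, channel identifiers and a per-sample exclusion mask.
#' Masked samples (e.g. amplifier-saturated segments during an impedance
#' measurement) are skipped by all analysis operations.
#'
#' @param samples Numeric matrix, one column per channel (a vector is treated
#'   as one channel), in volts.
#' @param fs Sampling rate in Hz.
#' @param channelIds Character vector of channel names.
#' @param excluded Logical per-sample exclusion mask (default all FALSE).
#' @return A \code{MeasurementTrace} object.
#' @export
MeasurementTrace <- function(samples, fs, channelIds = NULL, excluded = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1)
  if (is.null(channelIds)) channelIds <- paste0("ch", seq_len(ncol(samples)))
  if (is.null(excluded)) excluded <- rep(FALSE, nrow(samples))
  new("MeasurementTrace", samples = samples, fs = fs,
      channelIds = channelIds, excluded = excluded)
}

## ---------------------------------------------------------------------------
## Pattern-recognition pipeline
## ---------------------------------------------------------------------------

#' @rdname EpochConfig
#' @export
setClass("EpochConfig",
  representation(windowMs = "numeric", strideMs = "numeric", fs = "numeric")
)

setValidity("EpochConfig", function(object) {
  msg <- NULL
  stride <- object@strideMs * object@fs / 1000
  if (abs(stride - round(stride)) > 1e-9)
    msg <- c(msg, "strideMs * fs must give an integer number of samples")
  if (object@windowMs < object@strideMs)
    msg <- c(msg, "window must be at least one stride long")
  if (is.null(msg)) TRUE else msg
})

#' Epoching configuration
#'
#' Sliding-window segmentation: 128 ms analysis epochs advanced every 10 ms
#' (205 and 16 samples at 1600 Hz).
#'
#' @param windowMs Epoch length in ms (default 128).
#' @param strideMs Epoch advance in ms (default 10).
#' @param fs Sampling rate in Hz (default 1600).
#' @return An \code{EpochConfig} object.
#' @export
EpochConfig <- function(windowMs = 128, strideMs = 10, fs = 1600) {
  new("EpochConfig", windowMs = windowMs, strideMs = strideMs, fs = fs)
}

#' @rdname FeatureSpec
#' @export
setClass("FeatureSpec",
  representation(
    frequenciesHz = "numeric",
    smoothBins = "integer",
    nChannels = "integer"
  )
)

setValidity("FeatureSpec", function(object) {
  msg <- NULL
  if (length(object@frequenciesHz) != 8L)
    msg <- c(msg, "exactly 8 feature frequencies are required")
  if (object@smoothBins < 0) msg <- c(msg, "smoothBins must be >= 0")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Spectral feature specification
#'
#' Smoothed FFT power features read at eight fixed frequencies (31, 55, 78,
#' 102, 148, 195, 258 and 320 Hz) per channel: 24 features over 3 channels.
#' With the default 205-sample epoch at 1600 Hz the DFT bin width is
#' 1600/205 = 7.80 Hz and the eight frequencies fall within half a bin of
#' bins 4, 7, 10, 13, 19, 25, 33 and 41; the constructor asserts this for the
#' default configuration.
#'
#' @param frequenciesHz The eight feature frequencies in Hz.
#' @param smoothBins Moving-average half-width in bins applied to the power
#'   spectrum before reading the features (default 1, i.e. a 3-bin window).
#' @param nChannels Number of channels (default 3).
#' @param cfg An \code{EpochConfig} used to assert the frequency/bin mapping.
#' @return A \code{FeatureSpec} object.
#' @seealso [spectralFeatures()], [featureBinIndices()]
#' @export
FeatureSpec <- function(frequenciesHz = c(31, 55, 78, 102, 148, 195, 258, 320),
                        smoothBins = 1L, nChannels = 3L,
                        cfg = EpochConfig()) {
  if (any(frequenciesHz >= cfg@fs / 2))
    stop("feature frequencies must be below fs/2")
  spec <- new("FeatureSpec", frequenciesHz = as.numeric(frequenciesHz),
              smoothBins = as.integer(smoothBins),
              nChannels = as.integer(nChannels))
  w <- windowSamples(cfg)
  off <- frequenciesHz * w / cfg@fs - round(frequenciesHz * w / cfg@fs)
  if (any(abs(off) > 0.5))
    stop("feature frequencies do not fall within half a DFT bin of the epoch grid")
  spec
}

#' @rdname AnnModel
#' @export
setClass("AnnModel",
  representation(
    layerSizes = "integer",
    weights = "list",
    activation = "character",
    center = "numeric",
    scale = "numeric",
    trainParams = "list",
    lossTrace = "numeric",
    trained = "logical"
  )
)

setValidity("AnnModel", function(object) {
  msg <- NULL
  if (length(object@layerSizes) != 3L)
    msg <- c(msg, "layerSizes must be (input, hidden, output)")
  if (object@layerSizes[3] != length(.MOTIONS))
    msg <- c(msg, "output layer size must equal the number of motion classes")
  if (object@trained) {
    w <- object@weights
    ok <- identical(dim(w$W1), c(object@layerSizes[1], object@layerSizes[2])) &&
      identical(dim(w$W2), c(object@layerSizes[2], object@layerSizes[3])) &&
      length(w$b1) == object@layerSizes[2] && length(w$b2) == object@layerSizes[3]
    if (!ok) msg <- c(msg, "weight shapes inconsistent with layerSizes")
  }
  if (is.null(msg)) TRUE else msg
})

#' Feed-forward neural-network motion classifier
#'
#' A 3-layer 24-32-5 feed-forward network with logistic-sigmoid activations,
#' trained by full-batch backpropagation on mean-squared error against one-hot
#' targets. Inputs are standardized with statistics stored in the model.
#' Hyperparameter defaults (learning rate 0.1, 2000 passes, uniform(-0.5, 0.5)
#' seeded initialization) are configuration, not claims.
#'
#' @param layerSizes Integer length-3, node counts per layer.
#' @param learningRate Gradient-descent step size.
#' @param epochs Number of full-batch training passes.
#' @param seed Integer seed for the weight initialization.
#' @param initRange Half-width of the uniform initial-weight distribution.
#' @return An untrained \code{AnnModel}; see [trainAnn()].
#' @export
AnnModel <- function(layerSizes = c(24L, 32L, 5L), learningRate = 0.1,
                     epochs = 2000L, seed = 1L, initRange = 0.5) {
  new("AnnModel", layerSizes = as.integer(layerSizes), weights = list(),
      activation = "logistic", center = numeric(0), scale = numeric(0),
      trainParams = list(learningRate = learningRate,
                         epochs = as.integer(epochs),
                         seed = as.integer(seed), initRange = initRange),
      lossTrace = numeric(0), trained = FALSE)
}
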