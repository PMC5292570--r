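#' Accessors for MeasurementTrace
#'
#' @param x A [MeasurementTrace].
#' @param value Replacement logical mask (recycled scalar allowed).
#' @return \code{traceSamples}: the samples-by-channels voltage matrix;
#'   \code{sampleRate}: the sampling rate in Hz; \code{channelIds}: channel
#'   names; \code{excludedMask}: the per-sample exclusion mask;
#'   \code{nChannels}, \code{nSamples}: dimensions; \code{traceDuration}:
#'   length in seconds.
#' @name MeasurementTrace-accessors
NULL

#' @rdname MeasurementTrace-accessors
#' @export
setMethod("traceSamples", "MeasurementTrace", function(x) x@samples)

#' @rdname MeasurementTrace-accessors
#' @export
setMethod("sampleRate", "MeasurementTrace", function(x) x@fs)

#' @rdname MeasurementTrace-accessors
#' @export
setMethod("channelIds", "MeasurementTrace", function(x) x@channelIds)

#' @rdname MeasurementTrace-accessors
#' @export
setMethod("excludedMask", "MeasurementTrace", function(x) x@excluded)

#' @rdname MeasurementTrace-accessors
#' @export
setReplaceMethod("excludedMask", "MeasurementTrace", function(x, value) {
  if (length(value) == 1L) value <- rep(value, nrow(x@samples))
  x@excluded <- as.logical(value)
  validObject(x)
  x
})

#' @rdname MeasurementTrace-accessors
#' @export
setMethod("nChannels", "MeasurementTrace", function(x) ncol(x@samples))

#' @rdname MeasurementTrace-accessors
#' @export
setMethod("nSamples", "MeasurementTrace", function(x) nrow(x@samples))

#' @rdname MeasurementTrace-accessors
#' @export
setMethod("traceDuration", "MeasurementTrace", function(x) nrow(x@samples) / x@fs)

setMethod("show", "MeasurementTrace", function(object) {
  cat("MeasurementTrace:", nrow(object@samples), "samples x",
      ncol(object@samples), "channels @", object@fs, "Hz (",
      format(nrow(object@samples) / object@fs, digits = 4), "s )\n")
  cat("  channels:", paste(object@channelIds, collapse = ", "), "\n")
  cat("  excluded:", sum(object@excluded), "samples (",
      format(100 * mean(object@excluded), digits = 3), "% )\n")
  rng <- range(object@samples)
  cat("  range: [", format(rng[1], digits = 4), ",",
      format(rng[2], digits = 4), "] V\n")
})

setMethod("show", "ImpedanceState", function(object) {
  idx <- imbalanceIndices(object)
  cat("ImpedanceState (at 300 Hz):\n")
  cat(sprintf("  Z1 = %.0f ohm < %.1f deg  (+ R1 = %.0f ohm)\n",
              object@z1Mag, object@z1Phase, object@r1))
  cat(sprintf("  Z2 = %.0f ohm < %.1f deg  (+ R2 = %.0f ohm)\n",
              object@z2Mag, object@z2Phase, object@r2))
  cat(sprintf("  imbalance: |d|Z|| = %.0f ohm, |d(phase)| = %.2f deg\n",
              idx[["magDiff"]], idx[["phaseDiff"]]))
})

setMethod("show", "AnnModel", function(object) {
  cat("AnnModel:", paste(object@layerSizes, collapse = "-"),
      "feed-forward network,", object@activation, "activation\n")
  if (object@trained) {
    cat(sprintf("  trained (%d passes, final loss %.4g)\n",
                length(object@lossTrace), utils::tail(object@lossTrace, 1)))
  } else {
    cat("  untrained\n")
  }
})

setMethod("show", "SourceModel", function(object) {
  cat("SourceModel:", object@nChannels, "channels @", object@fs, "Hz, carrier",
      object@carrierBand[1], "-", object@carrierBand[2], "Hz\n")
  cat("  activation envelope (V RMS):\n")
  print(signif(object@envelope, 3))
})
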