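## Epoching and spectral feature extraction.

#' @rdname EpochConfig
#' @param cfg An [EpochConfig].
#' @export
windowSamples <- function(cfg) as.integer(round(cfg@windowMs * cfg@fs / 1000))

#' @rdname EpochConfig
#' @export
strideSamples <- function(cfg) as.integer(round(cfg@strideMs * cfg@fs / 1000))

#' Segment a trace into sliding epochs
#'
#' Offline convention: the first epoch starts at the first sample and one
#' epoch is emitted per stride, \code{floor((N - w)/s) + 1} in total (188 for
#' a 2 s trace at 128 ms / 10 ms). Streaming convention: a decision is made
#' every stride from the start of the trace using the trailing window, with a
#' pre-roll buffer of \code{w - s} samples prepended so that a 2 s trace
#' yields exactly 200 decisions. Epochs whose window overlaps any excluded
#' sample are flagged \code{skipped}.
#'
#' @param trace A [MeasurementTrace] at the config's sampling rate.
#' @param cfg An [EpochConfig].
#' @param streaming Use the streaming convention (default FALSE).
#' @param preroll Optional \code{(w - s) x nChannels} matrix used to pre-fill
#'   the streaming buffer; defaults to zeros.
#' @return A list with \code{epochs} (list of window-by-channel matrices),
#'   \code{start} (first-sample index of each window in the, possibly
#'   pre-rolled, trace) and \code{skipped} (logical).
#' @export
epochStream <- function(trace, cfg, streaming = FALSE, preroll = NULL) {
  stopifnot(is(trace, "MeasurementTrace"), is(cfg, "EpochConfig"))
  if (abs(sampleRate(trace) - cfg@fs) > 1e-9)
    stop("trace sampling rate does not match the epoch config")
  w <- windowSamples(cfg)
  s <- strideSamples(cfg)
  x <- traceSamples(trace)
  mask <- excludedMask(trace)
  if (streaming) {
    if (is.null(preroll)) preroll <- matrix(0, nrow = w - s, ncol = ncol(x))
    if (nrow(preroll) != w - s || ncol(preroll) != ncol(x))
      stop("preroll must be a (window - stride) x nChannels matrix")
    x <- rbind(preroll, x)
    mask <- c(rep(FALSE, w - s), mask)
  }
  n <- nrow(x)
  if (n < w) stop("trace shorter than one analysis window")
  starts <- seq(1L, n - w + 1L, by = s)
  epochs <- lapply(starts, function(i) x[i:(i + w - 1L), , drop = FALSE])
  skipped <- vapply(starts, function(i) any(mask[i:(i + w - 1L)]), logical(1))
  list(epochs = epochs, start = starts, skipped = skipped)
}

#' DFT bin indices of the feature frequencies
#'
#' @param spec A [FeatureSpec].
#' @param cfg An [EpochConfig].
#' @return Integer vector of 0-based DFT bin indices (bin k covers frequency
#'   \code{k * fs / w}); \code{c(4, 7, 10, 13, 19, 25, 33, 41)} for the
#'   defaults.
#' @export
featureBinIndices <- function(spec, cfg) {
  w <- windowSamples(cfg)
  as.integer(round(spec@frequenciesHz * w / cfg@fs))
}

#' Smoothed FFT power features of one epoch
#'
#' Per channel: one-sided magnitude-squared spectrum of the (unpadded) epoch,
#' moving-average smoothing over \code{2*smoothBins + 1} bins, power read at
#' the bin nearest each feature frequency. Channel-major concatenation
#' (channel 1's eight features first) gives the 24-value feature vector.
#' Features scale with the square of the signal amplitude.
#'
#' @param epoch A window-by-channels numeric matrix (one element of
#'   \code{epochStream(...)$epochs}).
#' @param spec A [FeatureSpec].
#' @param cfg An [EpochConfig].
#' @return Numeric vector of \code{8 * nChannels} non-negative powers (V^2),
#'   named \code{ch<i>_<freq>Hz}.
#' @export
spectralFeatures <- function(epoch, spec, cfg) {
  w <- windowSamples(cfg)
  if (!is.matrix(epoch) || nrow(epoch) != w)
    stop("epoch must be a matrix with exactly one analysis window of rows")
  if (ncol(epoch) != spec@nChannels)
    stop("epoch channel count does not match the feature spec")
  bins <- featureBinIndices(spec, cfg) + 1L   # 1-based into the half spectrum
  out <- vapply(seq_len(ncol(epoch)), function(ch) {
    p <- halfSpectrumPower(epoch[, ch])
    movingAverage(p, spec@smoothBins)[bins]
  }, numeric(length(bins)))
  v <- as.vector(out)
  names(v) <- as.vector(outer(paste0(spec@frequenciesHz, "Hz"),
                              paste0("ch", seq_len(spec@nChannels), "_"),
                              function(f, c) paste0(c, f)))
  v
}

#' Feature matrix of a whole trace
#'
#' Convenience wrapper: epochs a trace and stacks the spectral features of the
#' non-skipped epochs into a matrix.
#'
#' @inheritParams epochStream
#' @param spec A [FeatureSpec].
#' @return A numeric matrix, one row per retained epoch, with attribute
#'   \code{"start"} giving the window start indices.
#' @export
traceFeatures <- function(trace, spec = FeatureSpec(), cfg = EpochConfig(),
                          streaming = FALSE, preroll = NULL) {
  ep <- epochStream(trace, cfg, streaming = streaming, preroll = preroll)
  keep <- !ep$skipped
  if (!any(keep)) stop("all epochs overlap excluded samples")
  feats <- t(vapply(ep$epochs[keep], spectralFeatures,
                    numeric(8L * spec@nChannels), spec = spec, cfg = cfg))
  attr(feats, "start") <- ep$start[keep]
  feats
}
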