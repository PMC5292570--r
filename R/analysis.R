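## Evaluation computations: RMS envelopes, correlation, summaries, rest-state
## noise-level classification, band-power comparison.

#' Sliding RMS envelope
#'
#' Root-mean-square amplitude over a sliding window, advanced by a fixed
#' stride, per channel. Excluded samples are dropped from each window's mean;
#' a window with no retained samples yields \code{NA}.
#'
#' @param trace A [MeasurementTrace].
#' @param windowMs RMS window length in ms (default 100).
#' @param strideMs Window advance in ms (default 10).
#' @return A windows-by-channels matrix with attribute \code{"timeS"} (window
#'   center times in seconds).
#' @export
rmsEnvelope <- function(trace, windowMs = 100, strideMs = 10) {
  stopifnot(is(trace, "MeasurementTrace"))
  fs <- sampleRate(trace)
  w <- round(windowMs * fs / 1000)
  s <- max(1L, round(strideMs * fs / 1000))
  x <- traceSamples(trace)
  if (w > nrow(x)) stop("RMS window longer than the trace")
  keep <- !excludedMask(trace)
  starts <- seq(1L, nrow(x) - w + 1L, by = s)
  env <- vapply(seq_len(ncol(x)), function(ch) {
    x2 <- x[, ch]^2 * keep
    csx <- cumsum(c(0, x2))
    csk <- cumsum(c(0, keep))
    num <- csx[starts + w] - csx[starts]
    den <- csk[starts + w] - csk[starts]
    sqrt(ifelse(den > 0, num / den, NA_real_))
  }, numeric(length(starts)))
  env <- matrix(env, nrow = length(starts),
                dimnames = list(NULL, channelIds(trace)))
  attr(env, "timeS") <- (starts - 1 + w / 2) / fs
  env
}

#' Pearson correlation between two envelopes
#'
#' Standard product-moment correlation between two equal-length numeric
#' vectors (e.g. RMS envelopes of the same source seen through two electrode
#' types). \code{NA} pairs are dropped; zero variance in either argument is
#' an error, as the coefficient is then undefined.
#'
#' @param x,y Numeric vectors (or single-channel matrices) of equal length.
#' @return A list with \code{r}, \code{n} (pairs used).
#' @export
pearsonCorr <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("envelopes must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  list(r = stats::cor(x, y), n = length(x))
}

#' Mean and sample standard deviation
#'
#' Arithmetic mean and the n-1 sample SD, the convention under which the
#' packaged reference tables' printed Mean/SD rows reproduce exactly.
#' Rounding is left to presentation time.
#'
#' @param values Numeric vector (length >= 1; SD is \code{NA} for n < 2).
#' @return Named numeric \code{c(mean = , sd = )}.
#' @export
meanSd <- function(values) {
  if (length(values) == 0) stop("empty value list")
  c(mean = mean(values),
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_)
}

#' Accuracy-table means
#'
#' Unweighted means of a balanced long-format accuracy table (columns
#' \code{task}, \code{subject}, \code{electrode}, \code{accuracy} in percent):
#' per-task means, per-subject means, and the overall mean, per electrode
#' condition.
#'
#' @param table A complete long-format accuracy data.frame.
#' @return A list with data.frames \code{perTask}, \code{perSubject} and
#'   \code{overall}.
#' @export
accuracySummary <- function(table) {
  needed <- c("task", "subject", "electrode", "accuracy")
  if (!all(needed %in% names(table)))
    stop("table must have columns ", paste(needed, collapse = ", "))
  if (anyNA(table$accuracy)) stop("missing cells in the accuracy table")
  counts <- table(table$task, table$subject, table$electrode)
  if (length(unique(as.vector(counts))) != 1)
    stop("accuracy table is not balanced")
  agg <- function(by) stats::aggregate(accuracy ~ . , data = table[, c(by, "electrode", "accuracy")], FUN = mean)
  list(perTask = agg("task"),
       perSubject = agg("subject"),
       overall = stats::aggregate(accuracy ~ electrode, data = table, FUN = mean))
}

#' Classify the rest-state noise level of a trace
#'
#' Peak-amplitude banding of a rest-state recording, following the three
#' defined noise bands: level 1 if the peak stays below \code{vLo} ("little
#' noise"), level 3 if it reaches the \code{vMid}-to-rail band, level 2
#' otherwise. Excluded samples are ignored.
#'
#' @param restTrace A [MeasurementTrace] recorded with no motion commanded.
#' @param vLo Level-1 upper bound in volts (default 1; the published level
#'   definition gives no number for "little noise").
#' @param vMid Level-3 lower bound in volts (default 6).
#' @return Integer noise level (1, 2 or 3).
#' @export
classifyNoiseLevel <- function(restTrace, vLo = 1, vMid = 6) {
  stopifnot(is(restTrace, "MeasurementTrace"))
  if (!(0 < vLo && vLo < vMid)) stop("need 0 < vLo < vMid")
  x <- traceSamples(restTrace)[!excludedMask(restTrace), , drop = FALSE]
  if (length(x) == 0) stop("empty (or fully excluded) trace")
  peak <- max(abs(x))
  if (peak < vLo) 1L else if (peak >= vMid) 3L else 2L
}

## Total periodogram power of a trace below/above a split frequency,
## pooled over channels (DC bin excluded).
splitBandPower <- function(trace, splitHz) {
  fs <- sampleRate(trace)
  x <- traceSamples(trace)
  below <- 0; above <- 0
  for (ch in seq_len(ncol(x))) {
    p <- halfSpectrumPower(x[, ch])
    f <- halfSpectrumFreqs(nrow(x), fs)
    below <- below + sum(p[f > 0 & f <= splitHz])
    above <- above + sum(p[f > splitHz])
  }
  c(below = below, above = above)
}

#' Compare band powers of two traces around a split frequency
#'
#' Periodogram power below and above the split (default 150 Hz) for each
#' trace, with the b-over-a ratio per band — the comparison used to contrast
#' electrode types, whose spectra agree below 150 Hz but diverge above.
#'
#' @param traceA,traceB Two [MeasurementTrace] objects at the same rate.
#' @param splitHz Split frequency in Hz, inside (0, fs/2).
#' @return A list with \code{a}, \code{b} (each \code{c(below, above)} in
#'   V^2) and \code{ratioBoverA} (\code{c(below, above)}).
#' @export
bandPowerCompare <- function(traceA, traceB, splitHz = 150) {
  if (abs(sampleRate(traceA) - sampleRate(traceB)) > 1e-9)
    stop("traces must share a sampling rate")
  if (splitHz <= 0 || splitHz >= sampleRate(traceA) / 2)
    stop("split frequency must lie inside (0, fs/2)")
  a <- splitBandPower(traceA, splitHz)
  b <- splitBandPower(traceB, splitHz)
  list(a = a, b = b, ratioBoverA = b / a)
}

## Power in narrow bins around the mains harmonics and meter tone of a trace,
## used for interference-floor and level-ordering checks.
harmonicBandPower <- function(trace, freqs = c(50, 100, 150, 200, 250, 300),
                              halfWidthHz = 2) {
  fs <- sampleRate(trace)
  x <- traceSamples(trace)
  f <- halfSpectrumFreqs(nrow(x), fs)
  tot <- 0
  for (ch in seq_len(ncol(x))) {
    p <- halfSpectrumPower(x[, ch])
    for (f0 in freqs) tot <- tot + sum(p[abs(f - f0) <= halfWidthHz])
  }
  tot
}
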