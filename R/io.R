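## Signal file I/O and experiment configuration.
##
## CSV/TSV dialect: '#'-prefixed metadata header lines (`# fs=1600`,
## `# channels=a,b,c`), comma (or tab) separated sample rows, period decimal
## separator, one column per channel plus an optional `excluded` 0/1 column.
## WAV: minimal 16-bit PCM RIFF, voltages mapped linearly onto int16 with a
## fixed full-scale (default the 9 V rail), so a round-trip preserves samples
## to one quantization step (fullScale/32767).

signalFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("csv", "tsv", "wav"))
    stop("unsupported signal format: .", ext, " (use csv, tsv or wav)")
  ext
}

#' Read and write multi-channel signal files
#'
#' Lossless round-trip storage of a [MeasurementTrace]: exact for CSV/TSV
#' (samples written at full double precision, sampling rate and channel names
#' in `#` header lines, exclusion mask as a trailing 0/1 column), to 16-bit
#' quantization for WAV (sampling rate from the WAV header; voltages scaled
#' by \code{fullScale}; the exclusion mask is not representable in WAV and is
#' dropped).
#'
#' @param trace A [MeasurementTrace].
#' @param path File path; the extension (.csv, .tsv, .wav) selects the format.
#' @param fullScale WAV full-scale voltage (default 9).
#' @return \code{writeSignal}: the path, invisibly. \code{readSignal}: a
#'   [MeasurementTrace].
#' @export
writeSignal <- function(trace, path, fullScale = 9) {
  stopifnot(is(trace, "MeasurementTrace"))
  fmt <- signalFormat(path)
  x <- traceSamples(trace)
  if (fmt == "wav") {
    writeWav16(x, sampleRate(trace), path, fullScale)
    return(invisible(path))
  }
  sep <- if (fmt == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%s", format(sampleRate(trace), digits = 15)),
               sprintf("# channels=%s", paste(channelIds(trace), collapse = ","))),
             con)
  df <- as.data.frame(x)
  names(df) <- channelIds(trace)
  df$excluded <- as.integer(excludedMask(trace))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = sep, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeSignal
#' @export
readSignal <- function(path, fullScale = 9) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- signalFormat(path)
  if (fmt == "wav") {
    w <- readWav16(path, fullScale)
    return(MeasurementTrace(w$samples, fs = w$fs))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fsLine <- grep("^# fs=", hdr, value = TRUE)
  if (length(fsLine) != 1) stop("malformed header: expected one '# fs=' line")
  fs <- as.numeric(sub("^# fs=", "", fsLine))
  if (is.na(fs) || fs <= 0) stop("invalid sampling rate in header")
  chLine <- grep("^# channels=", hdr, value = TRUE)
  sep <- if (fmt == "csv") "," else "\t"
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = sep,
                          header = TRUE, check.names = FALSE)
  excluded <- NULL
  if ("excluded" %in% names(df)) {
    excluded <- as.logical(df$excluded)
    df$excluded <- NULL
  }
  channels <- names(df)
  if (length(chLine) == 1) {
    declared <- strsplit(sub("^# channels=", "", chLine), ",")[[1]]
    if (length(declared) != length(channels))
      stop("header channel count does not match data columns")
    channels <- declared
  }
  MeasurementTrace(as.matrix(df), fs = fs, channelIds = channels,
                   excluded = excluded)
}

## -- minimal 16-bit PCM RIFF/WAVE ------------------------------------------

writeWav16 <- function(samples, fs, path, fullScale) {
  q <- pmin(pmax(round(samples / fullScale * 32767), -32768), 32767)
  inter <- as.integer(t(q))                    # interleaved frames
  nCh <- ncol(samples)
  dataBytes <- 2L * length(inter)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(nCh, con, size = 2, endian = "little")
  writeBin(as.integer(round(fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(fs)) * nCh * 2L, con, size = 4, endian = "little")
  writeBin(nCh * 2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path)
}

readWav16 <- function(path, fullScale) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL; nCh <- NULL; samples <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      nCh <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, "raw", n = size - 8L)
    } else if (tag == "data") {
      inter <- readBin(con, integer(), n = size %/% 2L, size = 2,
                       endian = "little", signed = TRUE)
      samples <- t(matrix(inter, nrow = nCh))
    } else {
      readBin(con, "raw", n = size)
    }
  }
  if (is.null(fs) || is.null(samples)) stop("malformed WAV: missing fmt/data chunk")
  list(samples = samples / 32767 * fullScale, fs = fs)
}

## -- experiment configuration ----------------------------------------------

#' Default bench experiment configuration
#'
#' The configuration driving [runBench()]: source model, wet/PPy electrode
#' transfer pair, amplifier, filter chain, interference model, the three
#' noise-level specs, epoching/feature settings and network hyperparameters.
#'
#' @param trainSecondsPerClass Training-segment length per class in seconds.
#' @param testSecondsPerClass Held-out segment length per class in seconds.
#' @param annEpochs Training passes of the network.
#' @return A named list of configuration objects.
#' @export
defaultExperimentConfig <- function(trainSecondsPerClass = 4,
                                    testSecondsPerClass = 2,
                                    annEpochs = 2000L) {
  list(
    source = SourceModel(),
    wet = wetTransfer(),
    ppy = ppyTransfer(),
    amplifier = benchAmplifier(),
    filter = FilterChainSpec(),
    interference = InterferenceModel(),
    noiseLevels = noiseLevelSpecs(),
    epoch = EpochConfig(),
    features = FeatureSpec(),
    ann = AnnModel(epochs = annEpochs),
    trainSecondsPerClass = trainSecondsPerClass,
    testSecondsPerClass = testSecondsPerClass
  )
}

## Section -> constructor map for the YAML config reader.
.CONFIG_SECTIONS <- c("source", "wet", "ppy", "amplifier", "filter",
                      "interference", "epoch", "features", "ann",
                      "trainSecondsPerClass", "testSecondsPerClass")

#' Read an experiment configuration from a YAML file
#'
#' Overrides fields of [defaultExperimentConfig()] from a plain-text YAML
#' file. Only known section names and known fields within each section are
#' accepted; anything else is an error, so typos cannot silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A configuration list as from [defaultExperimentConfig()].
#' @export
readExperimentConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .CONFIG_SECTIONS)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  cfg <- defaultExperimentConfig()
  builders <- list(
    source = SourceModel, wet = ElectrodeTransfer, ppy = ElectrodeTransfer,
    amplifier = AmplifierSpec, filter = FilterChainSpec,
    interference = InterferenceModel, epoch = EpochConfig,
    features = FeatureSpec, ann = AnnModel
  )
  for (sec in names(raw)) {
    if (sec %in% c("trainSecondsPerClass", "testSecondsPerClass")) {
      cfg[[sec]] <- as.numeric(raw[[sec]])
      next
    }
    fn <- builders[[sec]]
    known <- names(formals(fn))
    unknownField <- setdiff(names(raw[[sec]]), known)
    if (length(unknownField))
      stop("unknown field(s) in section '", sec, "': ",
           paste(unknownField, collapse = ", "))
    args <- raw[[sec]]
    if (sec == "interference" && !is.null(args$harmonicAmplitudes))
      args$harmonicAmplitudes <- unlist(args$harmonicAmplitudes)
    if (sec == "interference" && !is.null(args$meterSchedule))
      args$meterSchedule <- matrix(unlist(args$meterSchedule), ncol = 2, byrow = TRUE)
    if (sec == "source" && !is.null(args$envelope))
      args$envelope <- matrix(unlist(args$envelope), nrow = 5, byrow = TRUE,
                              dimnames = list(motionLabels(), NULL))
    cfg[[sec]] <- do.call(fn, args)
  }
  cfg
}
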