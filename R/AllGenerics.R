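#' @rdname MeasurementTrace-accessors
#' @export
setGeneric("traceSamples", function(x) standardGeneric("traceSamples"))

#' @rdname MeasurementTrace-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname MeasurementTrace-accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @rdname MeasurementTrace-accessors
#' @export
setGeneric("excludedMask", function(x) standardGeneric("excludedMask"))

#' @rdname MeasurementTrace-accessors
#' @export
setGeneric("excludedMask<-", function(x, value) standardGeneric("excludedMask<-"))

#' @rdname MeasurementTrace-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname MeasurementTrace-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname MeasurementTrace-accessors
#' @export
setGeneric("traceDuration", function(x) standardGeneric("traceDuration"))

#' @rdname imbalanceIndices
#' @export
setGeneric("imbalanceIndices", function(state) standardGeneric("imbalanceIndices"))
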