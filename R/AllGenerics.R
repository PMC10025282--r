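#' @rdname responseArray
#' @export
setGeneric("responseArray", function(x, ...) standardGeneric("responseArray"))

#' @rdname getRecord
#' @export
setGeneric("getRecord", function(x, i, ...) standardGeneric("getRecord"))

#' @rdname accessors
#' @export
setGeneric("nSensors", function(x) standardGeneric("nSensors"))

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname selection-accessors
#' @export
setGeneric("featureStatus", function(x) standardGeneric("featureStatus"))

#' @rdname selection-accessors
#' @export
setGeneric("confirmedFeatures", function(x) standardGeneric("confirmedFeatures"))

#' @rdname report-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname report-accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname report-accessors
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))
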