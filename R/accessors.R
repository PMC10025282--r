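#' Construct a SensorArrayExperiment from a response array
#'
#' @param response numeric array \code{nSensors x T x n} (channels, time,
#'   records) or a matrix \code{(nSensors*T) x n} laid out sensor-major.
#' @param colData data.frame / DataFrame of per-record metadata; must contain
#'   \code{record_id}, \code{class_label} and \code{humidity}.
#' @param protocol exposure protocol list as returned by
#'   \code{\link{exposureProtocol}}.
#' @param sensorLabels character vector of 7 channel labels.
#' @param metadata extra experiment-level metadata list.
#' @return a \linkS4class{SensorArrayExperiment}.
#' @export
SensorArrayExperiment <- function(response, colData, protocol,
                                  sensorLabels = sensorLabelSet(),
                                  metadata = list()) {
  if (length(dim(response)) == 3L) {
    d <- dim(response)
    # channels x time x records -> sensor-major rows (time fastest within
    # each channel block)
    response <- matrix(aperm(response, c(2L, 1L, 3L)),
                       nrow = d[1L] * d[2L], ncol = d[3L])
    ns <- d[1L]; nt <- d[2L]
  } else {
    ns <- length(sensorLabels)
    nt <- nrow(response) / ns
  }
  stopifnot(nt == round(nt))
  time_s <- (seq_len(nt) - 1L) / protocol$sample_hz
  rd <- S4Vectors::DataFrame(
    sensor_id = rep(seq_len(ns) - 1L, each = nt),
    sensor_label = rep(sensorLabels, each = nt),
    time_s = rep(time_s, times = ns))
  se <- SummarizedExperiment(
    assays = list(response = response),
    rowData = rd,
    colData = S4Vectors::DataFrame(colData),
    metadata = c(list(protocol = protocol), metadata))
  new("SensorArrayExperiment", se)
}

#' Response series as a 3D array
#'
#' @param x a \linkS4class{SensorArrayExperiment}.
#' @return numeric array \code{nSensors x nTimepoints x n}.
#' @rdname responseArray
#' @export
setMethod("responseArray", "SensorArrayExperiment", function(x, ...) {
  ns <- nSensors(x); nt <- nTimepoints(x)
  array(assay(x, "response"), dim = c(nt, ns, ncol(x)),
        dimnames = list(NULL, unique(rowData(x)$sensor_label),
                        colnames(x))) |> aperm(c(2L, 1L, 3L))
})

#' Extract one record as a channels-by-time matrix
#'
#' @param x a \linkS4class{SensorArrayExperiment}.
#' @param i record index or name.
#' @return numeric matrix \code{nSensors x nTimepoints}.
#' @rdname getRecord
#' @export
setMethod("getRecord", "SensorArrayExperiment", function(x, i, ...) {
  ns <- nSensors(x); nt <- nTimepoints(x)
  m <- matrix(assay(x, "response")[, i], nrow = nt, ncol = ns)
  t(m)
})

#' Basic dimensional accessors
#'
#' \code{nSensors} returns the number of array channels, \code{nTimepoints}
#' the samples per record, \code{classLabels} the per-record class labels and
#' \code{sampleRate} the sampling rate in Hz.
#'
#' @param x a \linkS4class{SensorArrayExperiment}.
#' @name accessors
#' @rdname accessors
#' @export
setMethod("nSensors", "SensorArrayExperiment", function(x)
  length(unique(rowData(x)$sensor_id)))

#' @rdname accessors
#' @export
setMethod("nTimepoints", "SensorArrayExperiment", function(x)
  nrow(x) %/% nSensors(x))

#' @rdname accessors
#' @export
setMethod("classLabels", "SensorArrayExperiment", function(x)
  as.character(colData(x)$class_label))

#' @rdname accessors
#' @export
setMethod("classLabels", "GasFeatureSet", function(x)
  as.character(colData(x)$class_label))

#' @rdname accessors
#' @export
setMethod("sampleRate", "SensorArrayExperiment", function(x)
  metadata(x)$protocol$sample_hz)

#' Feature matrix (records x features) from a GasFeatureSet
#'
#' @param x a \linkS4class{GasFeatureSet}.
#' @return numeric matrix, one row per record, canonical feature names as
#'   column names.
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "GasFeatureSet"))
  t(assay(x, "features"))
}

#' Selection state accessors
#'
#' @param x a \linkS4class{SelectionState}.
#' @name selection-accessors
#' @rdname selection-accessors
#' @export
setMethod("featureStatus", "SelectionState", function(x) x@status)

#' @rdname selection-accessors
#' @export
setMethod("confirmedFeatures", "SelectionState", function(x)
  names(x@status)[x@status == "confirmed"])

#' Classification report accessors
#'
#' @param x a \linkS4class{ClassificationReport}.
#' @name report-accessors
#' @rdname report-accessors
#' @export
setMethod("accuracy", "ClassificationReport", function(x) x@meanAccuracy)

#' @rdname report-accessors
#' @export
setMethod("confusionMatrix", "ClassificationReport", function(x) x@confusion)

#' @rdname report-accessors
#' @export
setMethod("perClassMetrics", "ClassificationReport", function(x) x@perClass)

setMethod("show", "SensorArrayExperiment", function(object) {
  cat("SensorArrayExperiment:", ncol(object), "records,",
      nSensors(object), "channels x", nTimepoints(object), "samples\n")
  p <- metadata(object)$protocol
  if (!is.null(p))
    cat(sprintf("  protocol: %gs injection + %gs recovery @ %g Hz\n",
                p$injection_s, p$recovery_s, p$sample_hz))
  if (ncol(object))
    cat("  classes:", paste(sprintf("%s(%d)",
        names(table(classLabels(object))), table(classLabels(object))),
        collapse = " "), "\n")
})

setMethod("show", "GasFeatureSet", function(object) {
  cat("GasFeatureSet:", nrow(object), "features x", ncol(object),
      "records\n")
  fam <- table(rowData(object)$family)
  cat("  families:", paste(sprintf("%s(%d)", names(fam), fam),
                           collapse = " "), "\n")
  lq <- metadata(object)$low_quality_channels
  if (length(lq))
    cat("  low-quality channels zeroed:", paste(lq, collapse = ", "), "\n")
})

setMethod("show", "SelectionState", function(object) {
  tab <- table(factor(object@status,
                      levels = c("confirmed", "tentative", "rejected")))
  cat("SelectionState:", length(object@status), "features after",
      object@nIterations, "iterations\n")
  cat(sprintf("  confirmed %d | tentative %d | rejected %d (percentile %g)\n",
              tab["confirmed"], tab["tentative"], tab["rejected"],
              object@percentile))
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport: mean accuracy %.2f%% over %d iteration(s)\n",
              object@meanAccuracy, length(object@iterAccuracy)))
  if (!is.na(object@compressionRatio))
    cat(sprintf("  selection: mean %.2f features kept, compression ratio %.2f\n",
                mean(object@nSelected), object@compressionRatio))
  cat("  confusion matrix (rows = truth):\n")
  print(object@confusion)
})
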