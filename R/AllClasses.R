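#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SensorArrayExperiment: a set of sensor-array exposure measurements
#'
#' Container for multichannel chemiresistive response measurements. Each
#' column is one exposure record; rows are the (sensor, time) grid of the
#' exposure protocol, so the single \code{"response"} assay has dimension
#' \code{nSensors * nTimepoints} by \code{n} records. Row metadata carries
#' \code{sensor_id} (0-based channel index), \code{sensor_label} (DNA
#' functionalization) and \code{time_s}; column metadata carries the mixture
#' label (gases, ratio, total concentration in ppm, humidity), the derived
#' class label, replicate id and the per-record RNG seed. The exposure
#' protocol and generator configuration live in \code{metadata()}.
#'
#' @slot .. inherits all slots from \linkS4class{SummarizedExperiment}.
#' @export
setClass("SensorArrayExperiment", contains = "SummarizedExperiment")

setValidity("SensorArrayExperiment", function(object) {
  msg <- NULL
  if (!("response" %in% assayNames(object)))
    msg <- c(msg, "assay 'response' is required")
  rd <- rowData(object)
  need <- c("sensor_id", "sensor_label", "time_s")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  else {
    ns <- length(unique(rd$sensor_id))
    if (ns != 7L)
      msg <- c(msg, "exactly 7 sensor channels are required")
    if (nrow(object) %% ns != 0L)
      msg <- c(msg, "row count must be nSensors * nTimepoints")
  }
  if (ncol(object) > 0L) {
    cd <- colData(object)
    needc <- c("record_id", "class_label", "humidity")
    if (!all(needc %in% colnames(cd)))
      msg <- c(msg, paste("colData must contain:", paste(needc, collapse = ", ")))
    if ("response" %in% assayNames(object) &&
        !all(is.finite(assay(object, "response"))))
      msg <- c(msg, "response values must be finite")
  }
  if (is.null(msg)) TRUE else msg
})

#' GasFeatureSet: curve features for a set of measurements
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"features"} assay
#' holds the 840-dimensional featurization (7 contiguous sensor blocks of
#' 120 features) of each measurement record, one record per column. Row
#' metadata gives the canonical feature name, the sensor block and the
#' feature family; column metadata is copied from the source
#' \linkS4class{SensorArrayExperiment}.
#'
#' @export
setClass("GasFeatureSet", contains = "SummarizedExperiment")

setValidity("GasFeatureSet", function(object) {
  msg <- NULL
  if (!("features" %in% assayNames(object)))
    msg <- c(msg, "assay 'features' is required")
  rd <- rowData(object)
  need <- c("feature", "sensor_id", "family")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (ncol(object) > 0L && ("features" %in% assayNames(object)) &&
      !all(is.finite(assay(object, "features"))))
    msg <- c(msg, "feature values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' SelectionState: outcome of shadow-feature all-relevant selection
#'
#' Records, for every candidate feature, the final status
#' (\code{confirmed} / \code{tentative} / \code{rejected}), the number of
#' iterations in which the feature's importance Z score beat the shadow
#' threshold ("hits"), and the full Z-score history.
#'
#' @slot status named character vector, one of confirmed/tentative/rejected.
#' @slot hits named integer vector of hit counts.
#' @slot zHistory numeric matrix, iterations x features, importance Z scores
#'   (NA once a feature has been decided and dropped from the model).
#' @slot shadowThreshold numeric vector, per-iteration shadow Z threshold.
#' @slot nIterations integer, iterations actually run.
#' @slot percentile numeric, shadow-threshold percentile (100 = strict
#'   maximum-shadow-Z rule).
#' @slot seed integer RNG seed used.
#' @export
setClass("SelectionState",
  representation(status = "character", hits = "integer",
                 zHistory = "matrix", shadowThreshold = "numeric",
                 nIterations = "integer", percentile = "numeric",
                 seed = "integer"))

setValidity("SelectionState", function(object) {
  msg <- NULL
  if (!all(object@status %in% c("confirmed", "tentative", "rejected")))
    msg <- c(msg, "status values must be confirmed/tentative/rejected")
  if (length(object@hits) != length(object@status))
    msg <- c(msg, "hits and status must have equal length")
  if (any(object@hits > object@nIterations))
    msg <- c(msg, "hit counts cannot exceed the number of iterations")
  if (object@percentile < 0 || object@percentile > 100)
    msg <- c(msg, "percentile must lie in [0, 100]")
  if (is.null(msg)) TRUE else msg
})

#' ClassificationReport: evaluation summary for one classification run
#'
#' @slot meanAccuracy mean test accuracy in percent.
#' @slot iterAccuracy per-iteration test accuracies in percent.
#' @slot confusion aggregate confusion matrix (rows = truth, cols = predicted).
#' @slot perClass data.frame with precision, recall, f1 per class plus a
#'   degenerate-division flag.
#' @slot nSelected features retained per iteration (NA when selection off).
#' @slot compressionRatio candidate count / mean selected count (NA when
#'   selection off).
#' @slot details list: configuration echo, seeds, extra per-iteration traces.
#' @export
setClass("ClassificationReport",
  representation(meanAccuracy = "numeric", iterAccuracy = "numeric",
                 confusion = "matrix", perClass = "data.frame",
                 nSelected = "numeric", compressionRatio = "numeric",
                 details = "list"))

setValidity("ClassificationReport", function(object) {
  msg <- NULL
  if (length(object@meanAccuracy) != 1L ||
      object@meanAccuracy < 0 || object@meanAccuracy > 100)
    msg <- c(msg, "meanAccuracy must be a single value in [0, 100]")
  cm <- object@confusion
  if (length(cm) && (any(cm < 0) || any(cm != round(cm))))
    msg <- c(msg, "confusion matrix must hold nonnegative integer counts")
  if (is.null(msg)) TRUE else msg
})
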