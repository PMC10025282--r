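# On-disk dataset format: one long CSV (record_id, sensor_id, time_s,
# response_pct) plus a JSON sidecar with the per-record labels, protocol,
# seeds and configuration echo. Round-trips are lossless to full double
# precision.

#' Write / read a sensor-array dataset
#'
#' \code{writeSensorDataset} writes \code{dataset.csv} (long format:
#' record_id, sensor_id, time_s, response_pct), \code{metadata.json}
#' (labels, protocol, per-record seeds) and, when the dataset carries its
#' generator configuration, \code{config.json}.
#'
#' @param x a \linkS4class{SensorArrayExperiment}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeSensorDataset <- function(x, dir) {
  stopifnot(is(x, "SensorArrayExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- nTimepoints(x); ns <- nSensors(x)
  rd <- rowData(x)
  long <- data.table::data.table(
    record_id = rep(colnames(x), each = nrow(x)),
    sensor_id = rep(rd$sensor_id, times = ncol(x)),
    time_s = rep(rd$time_s, times = ncol(x)),
    response_pct = as.vector(assay(x, "response")))
  data.table::fwrite(long, file.path(dir, "dataset.csv"))
  meta <- list(
    protocol = metadata(x)$protocol[c("injection_s", "recovery_s",
                                      "sample_hz")],
    sensor_labels = unique(rd$sensor_label),
    records = as.data.frame(colData(x)))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  if (!is.null(metadata(x)$config))
    writeExperimentConfig(metadata(x)$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' @rdname writeSensorDataset
#' @export
readSensorDataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  long <- data.table::fread(file.path(dir, "dataset.csv"))
  protocol <- do.call(exposureProtocol, as.list(meta$protocol))
  recs <- meta$records
  ids <- recs$record_id
  nt <- protocol$n_samples
  ns <- length(meta$sensor_labels)
  resp <- matrix(NA_real_, nt * ns, length(ids),
                 dimnames = list(NULL, ids))
  ord <- order(match(long$record_id, ids), long$sensor_id, long$time_s)
  resp[] <- long$response_pct[ord]
  rownames(recs) <- ids
  config <- if (file.exists(file.path(dir, "config.json")))
    readExperimentConfig(file.path(dir, "config.json")) else NULL
  SensorArrayExperiment(resp, recs, protocol,
                        sensorLabels = meta$sensor_labels,
                        metadata = if (is.null(config)) list()
                          else list(config = config))
}

#' Write / read a feature matrix
#'
#' The CSV holds one row per record (first column \code{record_id}, then
#' one column per canonical feature name); the JSON sidecar echoes the
#' layout, class labels and low-quality mask.
#'
#' @param features a \linkS4class{GasFeatureSet}.
#' @param path CSV path; the sidecar is written next to it as
#'   \code{<stem>_meta.json}.
#' @export
writeFeatureCSV <- function(features, path) {
  stopifnot(is(features, "GasFeatureSet"))
  fm <- featureMatrix(features)
  dt <- data.table::data.table(record_id = rownames(fm))
  dt <- cbind(dt, data.table::as.data.table(fm))
  data.table::fwrite(dt, path)
  side <- sub("\\.csv$", "_meta.json", path)
  lay <- metadata(features)$layout
  jsonlite::write_json(list(
    layout = lay[setdiff(names(lay), "total")],
    class_label = classLabels(features),
    low_quality_channels = metadata(features)$low_quality_channels,
    snr = as.list(metadata(features)$snr)),
    side, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @return \code{readFeatureCSV}: list with the feature matrix
#'   (records x features) and the sidecar metadata.
#' @export
readFeatureCSV <- function(path) {
  dt <- data.table::fread(path)
  ids <- dt$record_id
  X <- as.matrix(dt[, -1L])
  rownames(X) <- ids
  side <- sub("\\.csv$", "_meta.json", path)
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else list()
  list(X = X, meta = meta)
}
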