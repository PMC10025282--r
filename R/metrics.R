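# Shared evaluation utilities: confusion-matrix metrics, PCA coordinates
# for visualization, and report serialization.

#' Classification metrics from label vectors
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param levels class label order for the confusion matrix; defaults to
#'   the sorted union of the labels.
#' @return list: \code{accuracy} (percent), \code{confusion} (rows =
#'   truth), \code{per_class} data.frame with precision/recall/F1 and a
#'   \code{degenerate} flag for division-by-zero classes, and macro
#'   averages.
#' @export
computeMetrics <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (is.null(levels)) levels <- sort(unique(c(y_true, y_pred)))
  yt <- factor(y_true, levels = levels)
  yp <- factor(y_pred, levels = levels)
  cm <- table(truth = yt, predicted = yp)
  cm <- matrix(as.integer(cm), nrow = nlevels(yt),
               dimnames = dimnames(cm))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  per_class <- data.frame(class = levels, precision = prec, recall = rec,
                          f1 = f1,
                          degenerate = (tp + fp == 0) | (tp + fn == 0),
                          row.names = NULL)
  list(accuracy = 100 * sum(tp) / sum(cm), confusion = cm,
       per_class = per_class,
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1))
}

#' PCA coordinates for visualization
#'
#' Mean-centered projection onto the top principal components, with a fixed
#' sign convention (the largest-magnitude loading of each component is made
#' positive) for reproducibility. Visualization only: classification never
#' operates on these scores.
#'
#' @param X records-x-features matrix (standardize beforehand if features
#'   are on different scales).
#' @param n_components number of components.
#' @return list: \code{scores}, \code{explained_variance} fractions
#'   (non-increasing, summing to <= 1), \code{loadings}.
#' @export
pcaCoordinates <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("at least 2 records are required")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) == 0L || all(pc$sdev < 1e-12))
    stop("matrix has rank 0 after centering")
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = sc, explained_variance = evr[seq_len(k)], loadings = rot)
}

#' Serialize a ClassificationReport
#'
#' Writes \code{<name>.json} (full report: accuracies, per-class metrics,
#' selection trace, configuration and seed echo) and
#' \code{<name>_confusion.csv}.
#'
#' @param report a \linkS4class{ClassificationReport}.
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return invisible character vector of the written paths.
#' @export
renderReport <- function(report, dir, name = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jp <- file.path(dir, paste0(name, ".json"))
  cp <- file.path(dir, paste0(name, "_confusion.csv"))
  jsonlite::write_json(reportToList(report), jp, auto_unbox = TRUE,
                       digits = NA, na = "null")
  cm <- cbind(truth = rownames(report@confusion),
              as.data.frame.matrix(report@confusion))
  data.table::fwrite(cm, cp)
  invisible(c(jp, cp))
}

#' @rdname renderReport
#' @export
reportToList <- function(report) {
  list(mean_accuracy = report@meanAccuracy,
       iter_accuracy = report@iterAccuracy,
       confusion = list(labels = rownames(report@confusion),
                        counts = unname(apply(report@confusion, 1L,
                                              as.integer, simplify = FALSE))),
       per_class = report@perClass,
       n_selected = report@nSelected,
       compression_ratio = report@compressionRatio,
       details = report@details[setdiff(names(report@details),
                                        c("loss_train", "loss_test"))],
       loss_train = report@details$loss_train,
       loss_test = report@details$loss_test)
}

#' @rdname renderReport
#' @param path path of a JSON report written by \code{renderReport}.
#' @export
readReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lab <- x$confusion$labels
  cnt <- x$confusion$counts
  cm <- if (is.matrix(cnt)) cnt else do.call(rbind, lapply(cnt, as.integer))
  storage.mode(cm) <- "integer"
  dimnames(cm) <- list(truth = lab, predicted = lab)
  det <- as.list(x$details)
  if (!is.null(x$loss_train)) det$loss_train <- x$loss_train
  if (!is.null(x$loss_test)) det$loss_test <- x$loss_test
  new("ClassificationReport",
      meanAccuracy = x$mean_accuracy,
      iterAccuracy = as.numeric(x$iter_accuracy),
      confusion = cm, perClass = as.data.frame(x$per_class),
      nSelected = as.numeric(x$n_selected),
      compressionRatio = as.numeric(x$compression_ratio),
      details = det)
}
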