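# Zero-phase denoising and the normalization/augmentation steps applied
# before network training.

# Steady-state initial filter state for a unit step (direct form II
# transposed), so a constant input yields a constant output from the first
# sample on.
.filterZi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1L]; a <- a / a[1L]
  if (n == 1L) return(numeric(0))
  A <- rbind(-a[-1L], cbind(diag(1, n - 2L), rep(0, n - 2L)))
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(1, n - 1L) - t(A), B)
}

# Direct form II transposed IIR difference equation with optional initial
# state.
.iirFilter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1L]; a <- a / a[1L]
  z <- if (is.null(zi)) numeric(n - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1L] * x[i] + z[1L]
    if (n > 2L)
      for (j in seq_len(n - 2L))
        z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * y[i]
    z[n - 1L] <- b[n] * x[i] - a[n] * y[i]
  }
  y
}

#' Zero-phase low-pass filter of one response series
#'
#' Applies a low-pass Butterworth IIR filter twice, once forward and once
#' backward, so the net phase shift is zero. Edge transients are controlled
#' by odd-reflection padding of \code{3 * (order + 1)} samples at both ends
#' (removed before returning) combined with steady-state initialization of
#' the filter state at each pass, so constant signals pass through exactly.
#'
#' @param x numeric response series.
#' @param order filter order (>= 1).
#' @param cutoff normalized cutoff frequency in cycles per sample, strictly
#'   inside (0, 0.5); default 0.05.
#' @return filtered series, same length as \code{x}.
#' @export
zeroPhaseFilter <- function(x, order = 3L, cutoff = 0.05) {
  if (order < 1L) stop("order must be >= 1")
  if (cutoff <= 0 || cutoff >= 0.5)
    stop("cutoff must lie strictly inside (0, 0.5)")
  pad <- 3L * (order + 1L)
  n <- length(x)
  if (n <= 3L * order || n <= pad + 1L)
    stop("series too short for the required edge padding")
  bf <- signal::butter(order, 2 * cutoff, type = "low")
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  zi <- .filterZi(bf$b, bf$a)
  fwd <- .iirFilter(bf$b, bf$a, xp, zi * xp[1L])
  m <- length(fwd)
  bwd <- .iirFilter(bf$b, bf$a, fwd[m:1L], zi * fwd[m])
  yp <- bwd[m:1L]
  yp[(pad + 1L):(pad + n)]
}

#' Zero-phase filter every channel of every record
#'
#' @param x a \linkS4class{SensorArrayExperiment}.
#' @param order,cutoff see \code{\link{zeroPhaseFilter}}.
#' @return a filtered \linkS4class{SensorArrayExperiment}; a
#'   \code{filtered = TRUE} flag is added to \code{metadata()}.
#' @export
filterDataset <- function(x, order = 3L, cutoff = 0.05) {
  stopifnot(is(x, "SensorArrayExperiment"))
  nt <- nTimepoints(x); ns <- nSensors(x)
  a <- assay(x, "response")
  out <- a
  for (j in seq_len(ncol(a))) {
    for (ch in seq_len(ns)) {
      idx <- ((ch - 1L) * nt + 1L):(ch * nt)
      out[idx, j] <- zeroPhaseFilter(a[idx, j], order, cutoff)
    }
  }
  assay(x, "response") <- out
  metadata(x)$filtered <- list(order = order, cutoff = cutoff)
  x
}

#' Normalize record heights to 1
#'
#' Divides every channel of a record by the record-level maximum absolute
#' response, so the largest magnitude within each record is exactly 1 while
#' the relative inter-channel selectivity pattern is preserved. All-zero
#' records are returned unchanged with a warning.
#'
#' @param x a \linkS4class{SensorArrayExperiment} or a channels-by-time
#'   numeric matrix for a single record.
#' @return same type as the input, height-normalized.
#' @export
normalizeHeight <- function(x) {
  if (is.matrix(x)) {
    if (!all(is.finite(x))) stop("non-finite values in record")
    m <- max(abs(x))
    if (m == 0) {
      warning("all-zero record left unchanged by normalizeHeight")
      return(x)
    }
    return(x / m)
  }
  stopifnot(is(x, "SensorArrayExperiment"))
  a <- assay(x, "response")
  if (!all(is.finite(a))) stop("non-finite values in dataset")
  for (j in seq_len(ncol(a))) {
    m <- max(abs(a[, j]))
    if (m == 0) {
      warning("all-zero record ", colnames(a)[j] %||% j,
              " left unchanged by normalizeHeight")
    } else a[, j] <- a[, j] / m
  }
  assay(x, "response") <- a
  metadata(x)$normalized <- TRUE
  x
}

#' Augment a dataset with noise-jittered copies
#'
#' Returns the original records plus \code{n_copies} copies of each record
#' with additive white noise, labels preserved. Intended for training data
#' only (the class balance is preserved exactly).
#'
#' @param x a \linkS4class{SensorArrayExperiment}, already normalized.
#' @param n_copies nonnegative integer copies per record.
#' @param noise_sd additive noise standard deviation, as a fraction of the
#'   unit height.
#' @param seed integer seed.
#' @return augmented \linkS4class{SensorArrayExperiment}; copies carry an
#'   \code{augmented_from} column in \code{colData()}.
#' @export
augmentNoise <- function(x, n_copies = 30L, noise_sd = 0.02, seed = 1L) {
  stopifnot(is(x, "SensorArrayExperiment"))
  if (n_copies < 0) stop("n_copies must be nonnegative")
  cd0 <- colData(x)
  cd0$augmented_from <- NA_character_
  colData(x) <- cd0
  if (n_copies == 0L) return(x)
  a <- assay(x, "response")
  set.seed(seed)
  blocks <- list(a)
  cds <- list(cd0)
  for (k in seq_len(n_copies)) {
    jit <- a + matrix(stats::rnorm(length(a), 0, noise_sd),
                      nrow(a), ncol(a))
    colnames(jit) <- paste0(colnames(a), "_aug", k)
    blocks[[k + 1L]] <- jit
    cdk <- cd0
    cdk$augmented_from <- cd0$record_id
    cdk$record_id <- paste0(cd0$record_id, "_aug", k)
    rownames(cdk) <- cdk$record_id
    cds[[k + 1L]] <- cdk
  }
  aa <- do.call(cbind, blocks)
  cda <- do.call(rbind, cds)
  se <- SummarizedExperiment(assays = list(response = aa),
                             rowData = rowData(x), colData = cda,
                             metadata = metadata(x))
  new("SensorArrayExperiment", se)
}
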