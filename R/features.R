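# Curve featurization: 120 features per channel (840 for the 7-channel
# array), spanning magnitudes, downsampled magnitudes (raw and
# height-normalized), first/second derivatives, interval differences,
# interval time constants, and interval areas.

#' Per-sensor feature layout
#'
#' Family counts for one 120-feature sensor block: the max-absolute
#' magnitude (1), max and min magnitude (2), downsampled magnitude,
#' downsampled normalized magnitude, max/min first derivative (2),
#' downsampled first derivative, max/min second derivative in the injection
#' and purge stages (2 + 2), interval differences, interval time constants
#' and interval areas. Counts are configurable but must total 120 per
#' sensor.
#'
#' @param mag_down,norm_down,d1_down downsample counts (defaults 30 each).
#' @param n_diff difference-interval count (default 5).
#' @param n_tc,n_area time-constant and area interval counts (default 8).
#' @return validated layout list with a \code{total} field.
#' @export
featureLayout <- function(mag_down = 30L, norm_down = 30L, d1_down = 30L,
                          n_diff = 5L, n_tc = 8L, n_area = 8L) {
  lay <- list(mag_abs_max = 1L, mag_extrema = 2L,
              mag_down = as.integer(mag_down),
              norm_down = as.integer(norm_down),
              d1_extrema = 2L, d1_down = as.integer(d1_down),
              d2_extrema = 4L, n_diff = as.integer(n_diff),
              n_tc = as.integer(n_tc), n_area = as.integer(n_area))
  lay$total <- with(lay, mag_abs_max + mag_extrema + mag_down + norm_down +
                      d1_extrema + d1_down + d2_extrema + n_diff + n_tc +
                      n_area)
  if (lay$total != 120L)
    stop("feature layout must total 120 per sensor, got ", lay$total)
  lay
}

#' Interval scheme for differences, time constants and areas
#'
#' Splits the record into contiguous index windows: the reaction (injection)
#' stage into 2 windows for differences and 4 for time constants/areas, the
#' purging stage into 3 and 4. Window boundaries are shared so contiguous
#' differences telescope.
#'
#' @param protocol an \code{\link{exposureProtocol}}.
#' @param n_diff_reaction,n_diff_purge difference-window counts per stage.
#' @param n_tc_reaction,n_tc_purge time-constant/area window counts per
#'   stage.
#' @return list with data.frames \code{diff} and \code{tc_area}
#'   (columns: start, end sample indices, stage).
#' @export
intervalScheme <- function(protocol = exposureProtocol(),
                           n_diff_reaction = 2L, n_diff_purge = 3L,
                           n_tc_reaction = 4L, n_tc_purge = 4L) {
  ni <- protocol$n_injection
  nt <- protocol$n_samples
  windows <- function(from, to, k) {
    br <- round(seq(from, to, length.out = k + 1L))
    data.frame(start = br[-length(br)], end = br[-1L])
  }
  d <- rbind(cbind(windows(1L, ni, n_diff_reaction), stage = "reaction"),
             cbind(windows(ni, nt, n_diff_purge), stage = "purge"))
  ta <- rbind(cbind(windows(1L, ni, n_tc_reaction), stage = "reaction"),
              cbind(windows(ni, nt, n_tc_purge), stage = "purge"))
  if (any(d$end <= d$start) || any(ta$end <= ta$start))
    stop("record too short for the requested interval scheme")
  list(diff = d, tc_area = ta, n_samples = nt, n_injection = ni,
       sample_hz = protocol$sample_hz)
}

# Stride-decimation indices: exactly k strictly increasing indices in 1..L.
.dsIdx <- function(L, k) {
  if (L < k) stop("series too short to downsample to ", k, " points")
  floor(seq(0, L - 1, length.out = k)) + 1L
}

#' Interval time constant of a response segment
#'
#' Threshold-crossing estimator. In \code{rise} mode the time constant is
#' the time from the segment start to the first crossing of
#' \code{start + (1 - exp(-1)) * (end - start)}; in \code{decay} mode it is
#' the time to first reach \code{exp(-1)} of the segment's initial value
#' (decay referenced to the zero asymptote). Flat segments return 0; a
#' threshold never reached returns the window duration.
#'
#' @param segment numeric response segment (length >= 5).
#' @param sample_hz sampling rate in Hz.
#' @param mode \code{"rise"} or \code{"decay"}.
#' @return time constant in seconds.
#' @export
computeTimeConstant <- function(segment, sample_hz = 1,
                                mode = c("rise", "decay")) {
  mode <- match.arg(mode)
  L <- length(segment)
  if (L < 5L) stop("segment must have at least 5 samples")
  s <- segment[1L]; e <- segment[L]
  tol <- 1e-12 + 1e-9 * max(abs(segment))
  if (max(abs(segment - s)) < tol) return(0)
  if (mode == "rise") {
    if (abs(e - s) < tol) return(0)
    thr <- s + (1 - exp(-1)) * (e - s)
    hit <- if (e > s) which(segment >= thr) else which(segment <= thr)
  } else {
    thr <- abs(s) * exp(-1)
    hit <- which(abs(segment) <= thr)
  }
  if (!length(hit)) return((L - 1) / sample_hz)
  (hit[1L] - 1L) / sample_hz
}

#' Trapezoidal area under a response segment
#'
#' @param segment numeric response segment (length >= 2).
#' @param sample_hz sampling rate in Hz.
#' @return signed area in percent-seconds.
#' @export
computeArea <- function(segment, sample_hz = 1) {
  L <- length(segment)
  if (L < 2L) stop("segment must have at least 2 samples")
  sum((segment[-L] + segment[-1L]) / 2) / sample_hz
}

#' Interval differences of a response series
#'
#' For each window of the scheme, the response at the window end minus the
#' response at the window start.
#'
#' @param series numeric response series.
#' @param scheme an \code{\link{intervalScheme}}.
#' @return numeric vector, one value per difference window.
#' @export
computeDifferences <- function(series, scheme) {
  if (length(series) < max(scheme$diff$end))
    stop("series shorter than the interval scheme")
  series[scheme$diff$end] - series[scheme$diff$start]
}

#' Derivative features of a response series
#'
#' First and second differences scaled by the sampling rate; extrema of the
#' second derivative are taken separately over the injection and purging
#' stages, and the downsampled derivative is the stride-decimated first
#' derivative.
#'
#' @param series numeric response series (filtered).
#' @param sample_hz sampling rate in Hz.
#' @param n_injection number of injection-stage samples.
#' @param n_down downsample count.
#' @return named list: \code{d1_max}, \code{d1_min}, \code{d1_down},
#'   \code{d2_inj_max}, \code{d2_inj_min}, \code{d2_pur_max},
#'   \code{d2_pur_min}.
#' @export
derivativeFeatures <- function(series, sample_hz = 1, n_injection,
                               n_down = 30L) {
  d1 <- diff(series) * sample_hz
  d2 <- diff(d1) * sample_hz
  # second-difference i spans samples i..i+2; stage assigned by its center
  ctr <- seq_along(d2) + 1L
  inj2 <- d2[ctr <= n_injection]
  pur2 <- d2[ctr > n_injection]
  rng <- function(v, f) if (length(v)) f(v) else 0
  list(d1_max = max(d1), d1_min = min(d1),
       d1_down = d1[.dsIdx(length(d1), n_down)],
       d2_inj_max = rng(inj2, max), d2_inj_min = rng(inj2, min),
       d2_pur_max = rng(pur2, max), d2_pur_min = rng(pur2, min))
}

# The full 120-feature block for one channel's series.
.sensorBlock <- function(y, scheme, layout) {
  hz <- scheme$sample_hz
  amax <- max(abs(y))
  mag_abs_max <- if (amax == 0) 0 else y[which.max(abs(y))]
  ynorm <- if (amax == 0) y else y / amax
  dv <- derivativeFeatures(y, hz, scheme$n_injection, layout$d1_down)
  ta <- scheme$tc_area
  tcs <- vapply(seq_len(nrow(ta)), function(i) {
    seg <- y[ta$start[i]:ta$end[i]]
    computeTimeConstant(seg, hz,
                        if (ta$stage[i] == "reaction") "rise" else "decay")
  }, numeric(1))
  areas <- vapply(seq_len(nrow(ta)), function(i)
    computeArea(y[ta$start[i]:ta$end[i]], hz), numeric(1))
  c(mag_abs_max, max(y), min(y),
    y[.dsIdx(length(y), layout$mag_down)],
    ynorm[.dsIdx(length(y), layout$norm_down)],
    dv$d1_max, dv$d1_min, dv$d1_down,
    dv$d2_inj_max, dv$d2_inj_min, dv$d2_pur_max, dv$d2_pur_min,
    computeDifferences(y, scheme),
    tcs, areas)
}

.blockNames <- function(layout) {
  c("magAbsMax", "magMax", "magMin",
    sprintf("magDown%02d", seq_len(layout$mag_down)),
    sprintf("magNormDown%02d", seq_len(layout$norm_down)),
    "d1Max", "d1Min",
    sprintf("d1Down%02d", seq_len(layout$d1_down)),
    "d2InjMax", "d2InjMin", "d2PurMax", "d2PurMin",
    sprintf("diff%d", seq_len(layout$n_diff)),
    sprintf("tc%d", seq_len(layout$n_tc)),
    sprintf("area%d", seq_len(layout$n_area)))
}

.blockFamilies <- function(layout) {
  rep(c("magnitude", "norm_magnitude", "derivative", "second_derivative",
        "difference", "time_constant", "area"),
      times = c(3L + layout$mag_down, layout$norm_down,
                2L + layout$d1_down, 4L, layout$n_diff, layout$n_tc,
                layout$n_area))
}

#' Extract the 840-dimensional feature vector of every record
#'
#' Concatenates the seven per-sensor 120-feature blocks in channel order.
#' Purely deterministic: no randomness enters featurization.
#'
#' @param x a (filtered) \linkS4class{SensorArrayExperiment}.
#' @param layout a \code{\link{featureLayout}}.
#' @param scheme an \code{\link{intervalScheme}}; derived from the dataset's
#'   protocol when NULL.
#' @return a \linkS4class{GasFeatureSet} (840 features x records).
#' @export
extractFeatures <- function(x, layout = featureLayout(), scheme = NULL) {
  stopifnot(is(x, "SensorArrayExperiment"))
  if (is.null(scheme)) {
    sch_d <- if (!is.null(metadata(x)$scheme)) metadata(x)$scheme
      else intervalScheme(metadata(x)$protocol)
    scheme <- sch_d
  }
  nt <- nTimepoints(x)
  if (nt != scheme$n_samples)
    stop("record length (", nt, ") inconsistent with interval scheme (",
         scheme$n_samples, ")")
  if (layout$n_diff != nrow(scheme$diff))
    stop("layout difference count does not match the interval scheme")
  if (layout$n_tc != nrow(scheme$tc_area) ||
      layout$n_area != nrow(scheme$tc_area))
    stop("layout tc/area counts do not match the interval scheme")
  ns <- nSensors(x)
  bn <- .blockNames(layout)
  labels <- unique(rowData(x)$sensor_label)
  fnames <- as.vector(vapply(seq_len(ns), function(ch)
    paste0("s", ch - 1L, "_", labels[ch], ".", bn), character(120L)))
  a <- assay(x, "response")
  fm <- matrix(0, nrow = 120L * ns, ncol = ncol(x),
               dimnames = list(fnames, colnames(x)))
  for (j in seq_len(ncol(x))) {
    for (ch in seq_len(ns)) {
      y <- a[((ch - 1L) * nt + 1L):(ch * nt), j]
      fm[((ch - 1L) * 120L + 1L):(ch * 120L), j] <-
        .sensorBlock(y, scheme, layout)
    }
  }
  rd <- S4Vectors::DataFrame(
    feature = fnames,
    sensor_id = rep(seq_len(ns) - 1L, each = 120L),
    sensor_label = rep(labels, each = 120L),
    family = rep(.blockFamilies(layout), times = ns))
  se <- SummarizedExperiment(assays = list(features = fm), rowData = rd,
                             colData = colData(x),
                             metadata = list(layout = layout,
                                             scheme = scheme))
  new("GasFeatureSet", se)
}

#' Per-channel signal-to-noise ratios of a dataset
#'
#' Signal: median over records of the channel's maximum absolute response.
#' Noise: median over records of \code{sd(diff(y)) / sqrt(2)}, a
#' plateau-insensitive white-noise estimate. Computed on the raw
#' (unfiltered) series.
#'
#' @param x a \linkS4class{SensorArrayExperiment}.
#' @return named numeric vector of SNRs, one per channel (Inf when the
#'   noise estimate is 0).
#' @export
channelSNR <- function(x) {
  stopifnot(is(x, "SensorArrayExperiment"))
  nt <- nTimepoints(x); ns <- nSensors(x)
  a <- assay(x, "response")
  labels <- unique(rowData(x)$sensor_label)
  snr <- vapply(seq_len(ns), function(ch) {
    idx <- ((ch - 1L) * nt + 1L):(ch * nt)
    sig <- stats::median(apply(abs(a[idx, , drop = FALSE]), 2L, max))
    noi <- stats::median(apply(a[idx, , drop = FALSE], 2L,
                               function(y) stats::sd(diff(y)) / sqrt(2)))
    if (noi == 0) Inf else sig / noi
  }, numeric(1))
  stats::setNames(snr, labels)
}

#' Zero the features of low-quality channels
#'
#' Channels whose dataset-level signal-to-noise ratio falls below the
#' threshold have their entire 120-feature block set to exactly 0 for every
#' record; the mask is recorded in \code{metadata()}.
#'
#' @param features a \linkS4class{GasFeatureSet}.
#' @param snr named per-channel SNR vector from \code{\link{channelSNR}}.
#' @param threshold SNR threshold (default 3, the conventional detection
#'   limit heuristic).
#' @return the masked \linkS4class{GasFeatureSet}.
#' @export
zeroLowQuality <- function(features, snr, threshold = 3) {
  stopifnot(is(features, "GasFeatureSet"))
  bad <- names(snr)[snr < threshold]
  if (length(bad)) {
    a <- assay(features, "features")
    a[rowData(features)$sensor_label %in% bad, ] <- 0
    assay(features, "features") <- a
  }
  metadata(features)$low_quality_channels <- bad
  metadata(features)$snr <- snr
  metadata(features)$snr_threshold <- threshold
  features
}
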