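# Declarative experiment configuration: one object drives simulation,
# preprocessing, featurization, selection and both classifiers.

#' Experiment configuration
#'
#' A single declarative description of one mixed-vapor discrimination
#' experiment. Defaults reproduce the default study conditions: 9 replicates
#' per mixture ratio at 10 ppm total, 3 replicates per pure-gas
#' concentration in \{2, 5, 10\} ppm, the 368 s + 114 s protocol at 1 Hz,
#' and the default amplitude/kinetics calibration.
#'
#' @param name experiment name.
#' @param gases character pair of gas names.
#' @param humidity \code{"low"}, \code{"high"} or \code{"shuffled"}
#'   (ratio classes pooled over both humidity levels).
#' @param class_schema \code{"ratios"} (3 mixing-ratio classes) or
#'   \code{"ratios+pure"} (ratios plus the two pure gases, 5 classes).
#' @param ratios list of integer ratio pairs.
#' @param mixture_total_ppm total concentration of mixture records.
#' @param pure_conc_ppm concentrations for pure-gas records.
#' @param mixture_reps,pure_reps replicate counts.
#' @param protocol an \code{\link{exposureProtocol}}.
#' @param noise a \code{\link{noiseConfig}}.
#' @param amplitude_table,time_constants generator calibration overrides.
#' @param conc_exponent sub-linear concentration-scaling exponent.
#' @param filter_params list(order, cutoff) of the zero-phase filter.
#' @param snr_threshold per-channel signal-to-noise threshold below which a
#'   channel's features are zeroed.
#' @param augment list(n_copies, noise_sd) for training-set augmentation.
#' @param boruta list of selection parameters (num_trees, n_rep, max_iter,
#'   alpha, percentile).
#' @param svm list of SVM search parameters (cost grid, gamma_scale grid,
#'   kernel).
#' @param mccv list(n_iterations, test_fraction, stratified).
#' @param cnn list of network hyperparameters, see \code{\link{cnnConfig}}.
#' @param seed master seed; every stage derives its own sub-stream from it.
#' @return an object of class \code{ExperimentConfig}.
#' @export
experimentConfig <- function(name = "experiment",
                             gases = c("NO2", "NH3"),
                             humidity = c("low", "high", "shuffled"),
                             class_schema = c("ratios", "ratios+pure"),
                             ratios = list(c(1, 1), c(1, 3), c(3, 1)),
                             mixture_total_ppm = 10,
                             pure_conc_ppm = c(2, 5, 10),
                             mixture_reps = 9L, pure_reps = 3L,
                             protocol = exposureProtocol(),
                             noise = noiseConfig(),
                             amplitude_table = defaultAmplitudeTable(),
                             time_constants = defaultTimeConstants(),
                             conc_exponent = 0.7,
                             filter_params = list(order = 3L, cutoff = 0.05),
                             snr_threshold = 3,
                             augment = list(n_copies = 30L, noise_sd = 0.02),
                             boruta = list(num_trees = 300L, n_rep = 1L,
                                           max_iter = 50L, alpha = 0.05,
                                           percentile = 90),
                             svm = list(cost = c(1, 10, 100),
                                        gamma_scale = c(0.1, 1, 10),
                                        kernel = "radial"),
                             mccv = list(n_iterations = 100L,
                                         test_fraction = 1/3,
                                         stratified = TRUE),
                             cnn = list(),
                             seed = 1L) {
  humidity <- match.arg(humidity)
  class_schema <- match.arg(class_schema)
  gases <- as.character(gases)
  if (length(gases) != 2L || !all(gases %in% .GASES))
    stop("gases must be a pair drawn from ", paste(.GASES, collapse = ", "))
  if (class_schema == "ratios+pure" && humidity == "shuffled")
    stop("the shuffled-humidity condition uses ratio classes only")
  if (length(ratios) == 0L && class_schema == "ratios")
    stop("empty class set")
  cfg <- list(name = name, gases = gases, humidity = humidity,
              class_schema = class_schema, ratios = ratios,
              mixture_total_ppm = mixture_total_ppm,
              pure_conc_ppm = pure_conc_ppm,
              mixture_reps = as.integer(mixture_reps),
              pure_reps = as.integer(pure_reps),
              protocol = protocol, noise = noise,
              amplitude_table = amplitude_table,
              time_constants = time_constants,
              conc_exponent = conc_exponent,
              filter_params = filter_params,
              snr_threshold = snr_threshold,
              augment = augment, boruta = boruta, svm = svm, mccv = mccv,
              cnn = cnn, seed = as.integer(seed))
  class(cfg) <- "ExperimentConfig"
  cfg
}

#' @export
print.ExperimentConfig <- function(x, ...) {
  cat("ExperimentConfig:", x$name, "\n")
  cat(sprintf("  gases %s-%s | humidity %s | schema %s | seed %d\n",
              x$gases[1], x$gases[2], x$humidity, x$class_schema, x$seed))
  invisible(x)
}

#' Shipped experiment presets
#'
#' The six gas-pair experiments (three 3-class low-humidity pairs, three
#' 5-class high-humidity pairs) plus the humidity-shuffled NH3-NO
#' demonstration.
#'
#' @param name preset name; see \code{presetNames()}.
#' @param seed master seed for the returned configuration.
#' @return an \code{\link{experimentConfig}}.
#' @export
presetConfig <- function(name, seed = 1L) {
  presets <- list(
    "NO2-NH3-low"      = list(gases = c("NO2", "NH3"), humidity = "low",
                              class_schema = "ratios"),
    "NO-NH3-low"       = list(gases = c("NO", "NH3"), humidity = "low",
                              class_schema = "ratios"),
    "NO-NO2-low"       = list(gases = c("NO", "NO2"), humidity = "low",
                              class_schema = "ratios"),
    "NH3-H2S-high"     = list(gases = c("NH3", "H2S"), humidity = "high",
                              class_schema = "ratios+pure"),
    "NH3-NO-high"      = list(gases = c("NH3", "NO"), humidity = "high",
                              class_schema = "ratios+pure"),
    "H2S-NO-high"      = list(gases = c("H2S", "NO"), humidity = "high",
                              class_schema = "ratios+pure"),
    "NH3-NO-shuffled"  = list(gases = c("NH3", "NO"), humidity = "shuffled",
                              class_schema = "ratios"))
  if (!name %in% names(presets))
    stop("unknown preset; available: ", paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  experimentConfig(name = name, gases = p$gases, humidity = p$humidity,
                   class_schema = p$class_schema, seed = seed)
}

#' @rdname presetConfig
#' @export
presetNames <- function() c("NO2-NH3-low", "NO-NH3-low", "NO-NO2-low",
                            "NH3-H2S-high", "NH3-NO-high", "H2S-NO-high",
                            "NH3-NO-shuffled")

#' Write / read an experiment configuration as JSON
#'
#' Scalar and vector fields are serialized directly; the calibration tables
#' are stored in long form. \code{readExperimentConfig} reconstructs a full
#' \code{ExperimentConfig}, filling unstated fields with defaults.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param path JSON file path.
#' @export
writeExperimentConfig <- function(config, path) {
  x <- unclass(config)
  x$amplitude_table <- .arrayToLong(config$amplitude_table)
  x$time_constants <- list(
    tau_ads = .matToLong(config$time_constants$tau_ads),
    tau_des = .matToLong(config$time_constants$tau_des))
  x$protocol <- config$protocol[c("injection_s", "recovery_s", "sample_hz")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeExperimentConfig
#' @export
readExperimentConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  amp <- .longToArray(x$amplitude_table)
  tc <- list(tau_ads = .longToMat(x$time_constants$tau_ads),
             tau_des = .longToMat(x$time_constants$tau_des))
  experimentConfig(
    name = x$name, gases = x$gases, humidity = x$humidity,
    class_schema = x$class_schema,
    ratios = {
      rm_ <- if (is.matrix(x$ratios)) x$ratios else do.call(rbind, x$ratios)
      lapply(seq_len(nrow(rm_)), function(i) as.numeric(rm_[i, ]))
    },
    mixture_total_ppm = x$mixture_total_ppm,
    pure_conc_ppm = x$pure_conc_ppm,
    mixture_reps = x$mixture_reps, pure_reps = x$pure_reps,
    protocol = do.call(exposureProtocol, as.list(x$protocol)),
    noise = do.call(noiseConfig, as.list(x$noise)),
    amplitude_table = amp, time_constants = tc,
    conc_exponent = x$conc_exponent,
    filter_params = as.list(x$filter_params),
    snr_threshold = x$snr_threshold,
    augment = as.list(x$augment), boruta = as.list(x$boruta),
    svm = as.list(x$svm), mccv = as.list(x$mccv),
    cnn = as.list(x$cnn), seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.arrayToLong <- function(a) {
  dn <- dimnames(a)
  g <- expand.grid(sensor = dn[[1]], gas = dn[[2]], humidity = dn[[3]],
                   stringsAsFactors = FALSE)
  g$amp <- as.vector(a)
  g
}

.longToArray <- function(df) {
  a <- array(NA_real_, dim = c(7L, 4L, 2L),
             dimnames = list(.SENSOR_LABELS, .GASES, c("low", "high")))
  for (i in seq_len(nrow(df)))
    a[df$sensor[i], df$gas[i], df$humidity[i]] <- df$amp[i]
  a
}

.matToLong <- function(m) {
  g <- expand.grid(sensor = rownames(m), gas = colnames(m),
                   stringsAsFactors = FALSE)
  g$tau <- as.vector(m)
  g
}

.longToMat <- function(df) {
  m <- matrix(NA_real_, 7L, 4L, dimnames = list(.SENSOR_LABELS, .GASES))
  for (i in seq_len(nrow(df))) m[df$sensor[i], df$gas[i]] <- df$tau[i]
  m
}
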