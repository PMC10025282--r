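# Synthetic sensor-array response generator. The noiseless core is
# first-order adsorption/desorption kinetics:
#   injection:  A (1 - exp(-t / tau_ads))
#   purge:      A_end exp(-(t - t_inj) / tau_des)
# with plateau A the ratio-weighted, signed combination of pure-gas
# amplitudes, scaled sub-linearly in total concentration. Five noise
# mechanisms (white noise, inter-measurement carry-over, switching spikes,
# slow thermal drift, sporadic step reactions) are layered on top.

#' Mixture label for one exposure
#'
#' @param gases character vector of 1 or 2 gas names (a pure gas is the
#'   degenerate ratio 1:0).
#' @param ratio integer pair of nonnegative mixing-ratio parts.
#' @param total_conc_ppm total concentration in ppm.
#' @param humidity \code{"low"} or \code{"high"}.
#' @return validated label list; the class label is derived
#'   deterministically (gas name for a pure gas, \code{"r1:r2"} otherwise).
#' @export
mixtureLabel <- function(gases, ratio = c(1, 0), total_conc_ppm = 10,
                         humidity = c("low", "high")) {
  humidity <- match.arg(humidity)
  gases <- as.character(gases)
  if (!all(gases %in% .GASES))
    stop("unknown gas: ", paste(setdiff(gases, .GASES), collapse = ", "))
  if (length(gases) == 1L) gases <- c(gases, gases)
  ratio <- as.numeric(ratio)
  if (length(ratio) != 2L || any(ratio < 0) || sum(ratio) == 0)
    stop("ratio must be two nonnegative parts, not both zero")
  if (total_conc_ppm < 0) stop("total_conc_ppm must be nonnegative")
  class_label <- if (ratio[2L] == 0) gases[1L]
    else if (ratio[1L] == 0) gases[2L]
    else paste0(ratio[1L], ":", ratio[2L])
  list(gases = gases, ratio = ratio, total_conc_ppm = total_conc_ppm,
       humidity = humidity, class_label = class_label)
}

#' Simulate one channel's response to one exposure
#'
#' @param sensor channel label (one of \code{\link{sensorLabelSet}()}) or
#'   1-based channel index.
#' @param label a \code{\link{mixtureLabel}}.
#' @param protocol an \code{\link{exposureProtocol}}.
#' @param noise a \code{\link{noiseConfig}}; defaults to noise off.
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @param amplitude_table plateau calibration array, see
#'   \code{\link{defaultAmplitudeTable}}.
#' @param time_constants list of tau matrices, see
#'   \code{\link{defaultTimeConstants}}.
#' @param conc_exponent exponent of the sub-linear power-law concentration
#'   scaling \code{(c/10)^p}; must lie in (0, 1].
#' @param prev_end final response value of the preceding record on this
#'   channel (drives the carry-over term).
#' @return numeric response series of length \code{protocol$n_samples},
#'   signed percent.
#' @export
simulateResponse <- function(sensor, label, protocol = exposureProtocol(),
                             noise = noiselessConfig(), seed = NULL,
                             amplitude_table = defaultAmplitudeTable(),
                             time_constants = defaultTimeConstants(),
                             conc_exponent = 0.7, prev_end = 0) {
  if (is.numeric(sensor)) sensor <- .SENSOR_LABELS[sensor]
  if (!sensor %in% rownames(amplitude_table))
    stop("unknown sensor: ", sensor)
  if (conc_exponent <= 0 || conc_exponent > 1)
    stop("conc_exponent must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)

  w <- label$ratio / sum(label$ratio)
  amps <- vapply(label$gases, function(g) {
    if (!g %in% colnames(amplitude_table))
      stop("amplitude_table does not cover gas ", g)
    a <- amplitude_table[sensor, g, label$humidity]
    if (is.na(a)) stop("amplitude_table does not cover gas ", g)
    a
  }, numeric(1))
  dirs <- .GAS_DIRECTION[label$gases]
  scale <- if (label$total_conc_ppm <= 0) 0
    else (label$total_conc_ppm / 10)^conc_exponent
  A <- scale * sum(w * dirs * amps)
  tau_a <- sum(w * time_constants$tau_ads[sensor, label$gases])
  tau_d <- sum(w * time_constants$tau_des[sensor, label$gases])

  n <- protocol$n_samples
  t <- (seq_len(n) - 1) / protocol$sample_hz
  inj <- t < protocol$injection_s
  y <- numeric(n)
  y[inj] <- A * (1 - exp(-t[inj] / tau_a))
  A_end <- A * (1 - exp(-protocol$injection_s / tau_a))
  y[!inj] <- A_end * exp(-(t[!inj] - protocol$injection_s) / tau_d)

  if (noise$carryover_frac > 0 && prev_end != 0)
    y <- y + noise$carryover_frac * prev_end * exp(-t / tau_d)
  if (noise$white_sd > 0)
    y <- y + stats::rnorm(n, 0, noise$white_sd)
  if (noise$switch_spike_prob > 0 && noise$switch_spike_amp > 0) {
    hit <- stats::rbinom(n, 1L, noise$switch_spike_prob)
    sgn <- sign(stats::runif(n) - 0.5)
    y <- y + hit * sgn * noise$switch_spike_amp
  }
  if (noise$drift_slope_sd > 0)
    y <- y + stats::rnorm(1, 0, noise$drift_slope_sd) * t
  if (noise$discrete_event_prob > 0 && noise$discrete_event_amp > 0 &&
      stats::runif(1) < noise$discrete_event_prob) {
    at <- sample.int(n, 1L)
    y[at:n] <- y[at:n] + sign(stats::runif(1) - 0.5) * noise$discrete_event_amp
  }
  y
}

#' Simulate a full sensor-array experiment
#'
#' Generates the record inventory implied by the experiment configuration:
#' by default 9 replicates per mixture-ratio class at the shared total
#' concentration, and (for the 5-class schema) 3 replicates per pure gas at
#' each of the pure-gas concentrations. Records carry deterministic
#' per-record seeds derived from the master seed; identical configuration
#' plus seed reproduces the dataset bit for bit. Under the
#' \code{"shuffled"} humidity condition the ratio-class inventory is
#' generated under both humidity levels and pooled with ratio-only class
#' labels.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @return a \linkS4class{SensorArrayExperiment}.
#' @export
simulateExperiment <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  plan <- .recordPlan(config)
  if (nrow(plan) == 0L) stop("empty class set: nothing to simulate")
  protocol <- config$protocol
  n <- protocol$n_samples
  resp <- array(0, dim = c(7L, n, nrow(plan)))
  prev_end <- numeric(7L)
  seeds <- integer(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    lab <- mixtureLabel(c(plan$gas1[i], plan$gas2[i]),
                        c(plan$ratio1[i], plan$ratio2[i]),
                        plan$total_conc_ppm[i], plan$humidity[i])
    seeds[i] <- deriveSeed(config$seed, i)
    set.seed(seeds[i])
    for (ch in 1:7) {
      resp[ch, , i] <- simulateResponse(
        ch, lab, protocol, config$noise, seed = NULL,
        amplitude_table = config$amplitude_table,
        time_constants = config$time_constants,
        conc_exponent = config$conc_exponent,
        prev_end = prev_end[ch])
      prev_end[ch] <- resp[ch, n, i]
    }
  }
  cd <- data.frame(
    record_id = sprintf("R%03d", seq_len(nrow(plan))),
    gas1 = plan$gas1, gas2 = plan$gas2,
    ratio1 = plan$ratio1, ratio2 = plan$ratio2,
    class_label = plan$class_label,
    total_conc_ppm = plan$total_conc_ppm,
    humidity = plan$humidity,
    replicate_id = plan$replicate_id,
    record_seed = seeds)
  rownames(cd) <- cd$record_id
  SensorArrayExperiment(resp, cd, protocol,
                        metadata = list(config = config))
}

# Expand an experiment configuration into one row per record.
.recordPlan <- function(config) {
  g <- config$gases
  hums <- switch(config$humidity,
                 low = "low", high = "high", shuffled = c("low", "high"))
  rows <- list()
  for (h in hums) {
    for (r in config$ratios) {
      cls <- paste0(r[1L], ":", r[2L])
      for (k in seq_len(config$mixture_reps))
        rows[[length(rows) + 1L]] <- data.frame(
          gas1 = g[1L], gas2 = g[2L], ratio1 = r[1L], ratio2 = r[2L],
          class_label = cls, total_conc_ppm = config$mixture_total_ppm,
          humidity = h, replicate_id = k)
    }
    if (identical(config$class_schema, "ratios+pure")) {
      for (gi in g) {
        for (conc in config$pure_conc_ppm) {
          for (k in seq_len(config$pure_reps))
            rows[[length(rows) + 1L]] <- data.frame(
              gas1 = gi, gas2 = gi, ratio1 = 1, ratio2 = 0,
              class_label = gi, total_conc_ppm = conc,
              humidity = h, replicate_id = k)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Noiseless plateau vector of a mixture label
#'
#' The 7-channel vector of noiseless end-of-injection responses, used for
#' separability diagnostics.
#'
#' @inheritParams simulateResponse
#' @return named numeric vector of length 7 (signed percent).
#' @export
plateauVector <- function(label, protocol = exposureProtocol(),
                          amplitude_table = defaultAmplitudeTable(),
                          time_constants = defaultTimeConstants(),
                          conc_exponent = 0.7) {
  vapply(1:7, function(ch) {
    y <- simulateResponse(ch, label, protocol, noiselessConfig(),
                          amplitude_table = amplitude_table,
                          time_constants = time_constants,
                          conc_exponent = conc_exponent)
    y[protocol$n_injection]
  }, numeric(1)) |> stats::setNames(.SENSOR_LABELS)
}
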