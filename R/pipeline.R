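# End-to-end orchestration: one declarative configuration drives
# simulation, filtering, featurization, selection, SVM/MCCV and the CNN,
# writing every intermediate artifact plus final reports.

#' Run a full experiment from one configuration
#'
#' Executes simulate -> filter -> featurize (with low-quality zeroing) ->
#' shadow-feature selection -> SVM/MCCV, and simulate -> normalize/augment
#' -> 1D CNN, writing the dataset CSV/JSON, the feature CSV, the selection
#' state JSON, and both classification reports into \code{out_dir}. Every
#' artifact is reproducible from the configuration and master seed alone.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param out_dir artifact directory (created if missing).
#' @param run_svm,run_cnn stage switches.
#' @param verbose log each stage with its seed.
#' @return invisibly, a list with the dataset, features, selection state
#'   and reports.
#' @export
runAll <- function(config, out_dir, run_svm = TRUE, run_cnn = TRUE,
                   verbose = TRUE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            sprintf(...))
  say("[simulate] experiment %s, master seed %d", config$name, config$seed)
  dataset <- simulateExperiment(config)
  writeSensorDataset(dataset, file.path(out_dir, "dataset"))

  say("[preprocess] zero-phase filter (order %d, cutoff %g)",
      config$filter_params$order, config$filter_params$cutoff)
  filtered <- filterDataset(dataset, config$filter_params$order,
                            config$filter_params$cutoff)

  say("[extract] 840-feature featurization")
  features <- extractFeatures(filtered)
  features <- zeroLowQuality(features, channelSNR(dataset),
                             config$snr_threshold)
  writeFeatureCSV(features, file.path(out_dir, "features.csv"))

  out <- list(dataset = dataset, features = features)
  if (run_svm) {
    say("[select] dataset-level selection snapshot (seed %d)",
        deriveSeed(config$seed, 41L))
    state <- runBoruta(featureMatrix(features), classLabels(features),
                       num_trees = config$boruta$num_trees,
                       n_rep = config$boruta$n_rep,
                       max_iter = config$boruta$max_iter,
                       alpha = config$boruta$alpha,
                       percentile = config$boruta$percentile,
                       seed = deriveSeed(config$seed, 41L))
    writeSelectionState(state, file.path(out_dir, "selection.json"))
    out$selection <- state

    say("[train-svm] %d MCCV iterations, selection inside each split",
        config$mccv$n_iterations)
    svm_report <- mccvEvaluate(features, select = TRUE,
                               boruta = config$boruta, svm = config$svm,
                               n_iterations = config$mccv$n_iterations,
                               test_fraction = config$mccv$test_fraction,
                               stratified = config$mccv$stratified,
                               seed = deriveSeed(config$seed, 43L))
    renderReport(svm_report, out_dir, "svm_report")
    out$svm_report <- svm_report
    say("[train-svm] mean MCCV accuracy %.2f%%", accuracy(svm_report))
  }
  if (run_cnn) {
    say("[train-cnn] stratified 2:1 split, %d epochs",
        config$cnn$epochs %||% 20L)
    cnn_report <- runCNNExperiment(dataset, cnn = config$cnn,
                                   augment = config$augment,
                                   split_seed = deriveSeed(config$seed, 47L),
                                   seed = deriveSeed(config$seed, 53L))
    renderReport(cnn_report, out_dir, "cnn_report")
    out$cnn_report <- cnn_report
    say("[train-cnn] test accuracy %.2f%%", accuracy(cnn_report))
  }
  invisible(out)
}
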