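# Multiclass soft-margin SVM with Monte-Carlo cross-validation. Every
# iteration draws a stratified random train/test split and refits the whole
# pipeline (scaler, optional selection, hyperparameter search, SVM) on the
# training split only.

# Stratified split: per class, round(n_c * test_fraction) test records
# (at least 1, at most n_c - 1). Deterministic under seed.
.stratifiedSplit <- function(y, test_fraction = 1/3, seed = 1L,
                             stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  set.seed(seed)
  n <- length(y)
  if (!stratified) {
    test <- sample.int(n, max(1L, round(n * test_fraction)))
    return(list(train = setdiff(seq_len(n), test), test = sort(test)))
  }
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < 2L)
      stop("class ", cl, " has fewer than 2 records")
    k <- min(length(idx) - 1L, max(1L, round(length(idx) * test_fraction)))
    test <- c(test, sample(idx, k))
  }
  list(train = setdiff(seq_len(n), sort(test)), test = sort(test))
}

# z-score standardization fit on the training split only.
.standardizeTrainTest <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(train = sweep(sweep(Xtr, 2L, mu), 2L, sd, "/"),
       test = sweep(sweep(Xte, 2L, mu), 2L, sd, "/"),
       center = mu, scale = sd)
}

#' Fit a multiclass SVM with inner hyperparameter search
#'
#' Radial-basis (default) soft-margin SVM with one-vs-one multiclass
#' voting. The cost and kernel-width grids are searched by stratified
#' k-fold cross-validation inside the training data only; ties break toward
#' the first grid entry (grids should be ordered from least to most
#' flexible).
#'
#' @param X standardized training feature matrix.
#' @param y training labels.
#' @param cost soft-margin parameter grid.
#' @param gamma_scale RBF width grid, as multiples of \code{1/ncol(X)}.
#' @param kernel \code{"radial"} or \code{"linear"}.
#' @param inner_folds folds of the inner search (default 3).
#' @param seed integer seed for the inner folds.
#' @return list: the fitted \code{e1071::svm} model plus the chosen
#'   hyperparameters.
#' @export
fitSvm <- function(X, y, cost = c(1, 10, 100), gamma_scale = c(0.1, 1, 10),
                   kernel = "radial", inner_folds = 3L, seed = 1L) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("training data must contain at least 2 classes")
  if (any(cost <= 0) || any(gamma_scale <= 0))
    stop("hyperparameter grids must be positive")
  gammas <- if (kernel == "linear") 1 else gamma_scale / max(1L, ncol(X))
  grid <- expand.grid(cost = cost, gamma = gammas)
  best <- NULL; best_acc <- -1
  folds <- .innerFolds(y, inner_folds, seed)
  for (g in seq_len(nrow(grid))) {
    accs <- vapply(folds, function(hold) {
      tr <- setdiff(seq_along(y), hold)
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- e1071::svm(x = X[tr, , drop = FALSE], y = droplevels(y[tr]),
                        scale = FALSE, kernel = kernel,
                        cost = grid$cost[g], gamma = grid$gamma[g])
      mean(as.character(stats::predict(fit, X[hold, , drop = FALSE])) ==
             as.character(y[hold]))
    }, numeric(1))
    acc <- mean(accs, na.rm = TRUE)
    if (is.finite(acc) && acc > best_acc + 1e-12) {
      best_acc <- acc; best <- g
    }
  }
  if (is.null(best)) best <- 1L
  model <- e1071::svm(x = X, y = y, scale = FALSE, kernel = kernel,
                      cost = grid$cost[best], gamma = grid$gamma[best])
  list(model = model, cost = grid$cost[best], gamma = grid$gamma[best],
       kernel = kernel, inner_accuracy = best_acc)
}

.innerFolds <- function(y, k, seed) {
  set.seed(seed)
  k <- max(2L, min(k, min(table(y))))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}

#' Monte-Carlo cross-validated pipeline evaluation
#'
#' Per iteration: a stratified random train/test split is drawn, the
#' feature scaler (and, when selection is active, the shadow-feature
#' selection and the SVM hyperparameter search) is refit on the training
#' split only, and accuracy is measured on the held-out split. Reports the
#' mean accuracy, the per-iteration trace, the aggregate confusion matrix,
#' per-class precision/recall/F1, and (with selection) the per-iteration
#' selected-feature counts and the compression ratio.
#'
#' @param features a \linkS4class{GasFeatureSet}, or a records-x-features
#'   matrix (then \code{labels} is required).
#' @param labels class labels (taken from \code{colData()} when
#'   \code{features} is a \linkS4class{GasFeatureSet}).
#' @param select logical: run shadow-feature selection inside each training
#'   split.
#' @param boruta list of selection parameters (see \code{\link{runBoruta}}).
#' @param svm list of SVM search parameters (see \code{\link{fitSvm}}).
#' @param n_iterations,test_fraction,stratified MCCV design.
#' @param classifier \code{"svm"} or \code{"majority"} (a majority-class
#'   dummy baseline).
#' @param n_candidate candidate count for the compression ratio; defaults
#'   to the number of features outside zeroed low-quality blocks.
#' @param seed master seed; iteration i uses a sub-seed derived from it.
#' @return a \linkS4class{ClassificationReport}.
#' @export
mccvEvaluate <- function(features, labels = NULL, select = TRUE,
                         boruta = list(), svm = list(),
                         n_iterations = 100L, test_fraction = 1/3,
                         stratified = TRUE, classifier = c("svm", "majority"),
                         n_candidate = NULL, seed = 1L) {
  classifier <- match.arg(classifier)
  if (is(features, "GasFeatureSet")) {
    X <- featureMatrix(features)
    if (is.null(labels)) labels <- classLabels(features)
    if (is.null(n_candidate)) {
      lq <- metadata(features)$low_quality_channels
      n_candidate <- ncol(X) - 120L * length(lq)
    }
  } else {
    X <- as.matrix(features)
    if (is.null(labels)) stop("labels are required with a plain matrix")
    if (is.null(n_candidate)) n_candidate <- ncol(X)
  }
  y <- factor(labels)
  if (any(table(y) < 2L)) stop("every class needs at least 2 records")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  bor <- utils::modifyList(list(num_trees = 300L, n_rep = 1L,
                                max_iter = 50L, alpha = 0.05,
                                percentile = 90), boruta)
  svmc <- utils::modifyList(list(cost = c(1, 10, 100),
                                 gamma_scale = c(0.1, 1, 10),
                                 kernel = "radial"), svm)
  lev <- levels(y)
  acc <- numeric(n_iterations)
  nsel <- rep(NA_real_, n_iterations)
  all_true <- character(0); all_pred <- character(0)
  fallback <- 0L
  for (i in seq_len(n_iterations)) {
    si <- deriveSeed(seed, i)
    sp <- .stratifiedSplit(y, test_fraction, seed = si,
                           stratified = stratified)
    std <- .standardizeTrainTest(X[sp$train, , drop = FALSE],
                                 X[sp$test, , drop = FALSE])
    Xtr <- std$train; Xte <- std$test
    ytr <- y[sp$train]; yte <- y[sp$test]
    if (select) {
      st <- runBoruta(Xtr, ytr, num_trees = bor$num_trees,
                      n_rep = bor$n_rep, max_iter = bor$max_iter,
                      alpha = bor$alpha, percentile = bor$percentile,
                      seed = deriveSeed(si, 17L))
      keep <- st@status == "confirmed"
      if (!any(keep)) {
        keep <- st@status != "rejected"
        fallback <- fallback + 1L
      }
      if (!any(keep)) keep <- rep(TRUE, ncol(Xtr))
      nsel[i] <- sum(keep)
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
    }
    if (classifier == "majority") {
      pred <- rep(names(which.max(table(ytr))), length(yte))
    } else {
      fit <- fitSvm(Xtr, ytr, cost = svmc$cost,
                    gamma_scale = svmc$gamma_scale, kernel = svmc$kernel,
                    seed = deriveSeed(si, 23L))
      pred <- as.character(stats::predict(fit$model, Xte))
    }
    acc[i] <- 100 * mean(pred == as.character(yte))
    all_true <- c(all_true, as.character(yte))
    all_pred <- c(all_pred, pred)
  }
  met <- computeMetrics(all_true, all_pred, levels = lev)
  cr <- if (select) compressionRatio(n_candidate, mean(nsel)) else NA_real_
  new("ClassificationReport",
      meanAccuracy = mean(acc), iterAccuracy = acc,
      confusion = met$confusion, perClass = met$per_class,
      nSelected = nsel, compressionRatio = cr,
      details = list(selection = select, classifier = classifier,
                     n_candidate = n_candidate, seed = seed,
                     n_iterations = n_iterations,
                     test_fraction = test_fraction,
                     selection_fallbacks = fallback,
                     boruta = bor, svm = svmc))
}

#' Paired comparison of the pipeline with and without selection
#'
#' Runs \code{\link{mccvEvaluate}} twice with identical split seeds (a
#' paired design) and reports both arms plus the per-iteration paired
#' accuracy differences (selection minus no-selection).
#'
#' @inheritParams mccvEvaluate
#' @return list with elements \code{with}, \code{without} (both
#'   \linkS4class{ClassificationReport}) and \code{paired_diff}.
#' @export
compareSelection <- function(features, labels = NULL, boruta = list(),
                             svm = list(), n_iterations = 100L,
                             test_fraction = 1/3, stratified = TRUE,
                             seed = 1L) {
  with_sel <- mccvEvaluate(features, labels, select = TRUE, boruta = boruta,
                           svm = svm, n_iterations = n_iterations,
                           test_fraction = test_fraction,
                           stratified = stratified, seed = seed)
  without <- mccvEvaluate(features, labels, select = FALSE, svm = svm,
                          n_iterations = n_iterations,
                          test_fraction = test_fraction,
                          stratified = stratified, seed = seed)
  list(with = with_sel, without = without,
       paired_diff = with_sel@iterAccuracy - without@iterAccuracy)
}
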