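# All-relevant feature selection with shadow features. Each iteration
# shuffles a shadow copy of every still-active feature, fits random forests
# on [real | shadow], converts importances to Z scores, and counts a "hit"
# whenever a real feature's Z beats the chosen percentile of the shadow Z
# scores (percentile 100 = the strict maximum-shadow rule). Two-sided
# binomial tests on the hit counts, Bonferroni-corrected over the undecided
# features, promote to confirmed or demote to rejected.

#' Run shadow-feature all-relevant selection
#'
#' @param X numeric feature matrix (records x features) with column names.
#' @param y class labels (factor or coercible).
#' @param num_trees trees per forest repetition.
#' @param n_rep forest repetitions per iteration; the importance score of
#'   an iteration is the mean impurity importance over repetitions.
#' @param max_iter maximum iterations.
#' @param alpha significance level of the binomial hit tests (Bonferroni
#'   corrected over the undecided features).
#' @param percentile shadow-threshold percentile in [0, 100]; 100 compares
#'   against the maximum shadow Z.
#' @param seed integer seed; the run is fully deterministic under it.
#' @return a \linkS4class{SelectionState}.
#' @export
runBoruta <- function(X, y, num_trees = 300L, n_rep = 1L, max_iter = 50L,
                      alpha = 0.05, percentile = 90, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!all(is.finite(X))) stop("X must contain only finite values")
  y <- factor(y)
  if (nlevels(y) < 2L) stop("y must contain at least 2 classes")
  if (any(table(y) < 2L)) stop("every class needs at least 2 records")
  if (max_iter < 1L) stop("max_iter must be >= 1")

  p <- ncol(X)
  feats <- colnames(X)
  status <- stats::setNames(rep("tentative", p), feats)
  hits <- stats::setNames(integer(p), feats)
  zhist <- matrix(NA_real_, nrow = 0L, ncol = p,
                  dimnames = list(NULL, feats))
  thr_hist <- numeric(0)
  iter <- 0L
  while (iter < max_iter && any(status == "tentative")) {
    iter <- iter + 1L
    set.seed(deriveSeed(seed, iter))
    active <- which(status != "rejected")
    Xa <- X[, active, drop = FALSE]
    sh <- apply(Xa, 2L, sample)
    colnames(sh) <- paste0(".shadow.", colnames(Xa))
    Xfull <- cbind(Xa, sh)
    imp <- matrix(NA_real_, n_rep, ncol(Xfull))
    for (r in seq_len(n_rep)) {
      fit <- ranger::ranger(x = Xfull, y = y, num.trees = num_trees,
                            importance = "impurity",
                            seed = deriveSeed(seed, iter * 1000L + r),
                            num.threads = 1L)
      imp[r, ] <- fit$variable.importance
    }
    # importance score: mean impurity importance over forest repetitions.
    # (Studentizing by the bootstrap s.e. is scale-invariant, which lets
    # weak-but-stable shadows outscore strongly informative features; the
    # magnitude comparison is the one that carries the signal.)
    z <- if (n_rep > 1L) colMeans(imp) else imp[1L, ]
    names(z) <- colnames(Xfull)
    zr <- z[seq_len(ncol(Xa))]
    zs <- z[-seq_len(ncol(Xa))]
    thr <- stats::quantile(zs, percentile / 100, names = FALSE)
    thr_hist <- c(thr_hist, thr)
    row <- rep(NA_real_, p)
    row[active] <- zr
    zhist <- rbind(zhist, row)
    und <- which(status == "tentative")
    hit_now <- names(which(zr > thr))
    hits[intersect(hit_now, feats[und])] <-
      hits[intersect(hit_now, feats[und])] + 1L
    m <- length(und)
    if (m > 0L) {
      pc <- alpha / m
      p_hi <- stats::pbinom(hits[und] - 1L, iter, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[und], iter, 0.5)
      status[und][p_hi < pc] <- "confirmed"
      status[und][p_lo < pc & p_hi >= pc] <- "rejected"
    }
  }
  new("SelectionState", status = status, hits = hits, zHistory = zhist,
      shadowThreshold = thr_hist, nIterations = iter,
      percentile = as.numeric(percentile), seed = as.integer(seed))
}

#' Reduce a feature matrix to the selected columns
#'
#' @param X feature matrix whose columns the selection state was computed
#'   on.
#' @param state a \linkS4class{SelectionState}.
#' @param tentative \code{"drop"} (default) or \code{"keep"} undecided
#'   features.
#' @return the reduced matrix, column names preserved.
#' @export
selectColumns <- function(X, state, tentative = c("drop", "keep")) {
  tentative <- match.arg(tentative)
  X <- as.matrix(X)
  if (!identical(colnames(X), names(state@status)))
    stop("selection state does not match the matrix columns")
  keep <- state@status == "confirmed"
  if (tentative == "keep") keep <- keep | state@status == "tentative"
  if (!any(keep))
    stop("no features selected: refusing to fit an empty model")
  X[, keep, drop = FALSE]
}

#' Feature-compression ratio
#'
#' Candidate feature count divided by the mean number of selected features.
#'
#' @param n_candidate candidate feature count.
#' @param n_selected_mean mean selected-feature count (> 0).
#' @return the ratio.
#' @export
compressionRatio <- function(n_candidate, n_selected_mean) {
  if (n_selected_mean <= 0) stop("mean selected count must be positive")
  n_candidate / n_selected_mean
}

#' Serialize / restore a SelectionState
#'
#' @param state a \linkS4class{SelectionState}.
#' @param path JSON file path.
#' @export
writeSelectionState <- function(state, path) {
  jsonlite::write_json(list(
    status = as.list(state@status), hits = as.list(state@hits),
    n_iterations = state@nIterations, percentile = state@percentile,
    seed = state@seed, shadow_threshold = state@shadowThreshold),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeSelectionState
#' @export
readSelectionState <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SelectionState",
      status = unlist(x$status), hits = as.integer(unlist(x$hits)) |>
        stats::setNames(names(x$hits)),
      zHistory = matrix(NA_real_, 0L, length(x$status),
                        dimnames = list(NULL, names(x$status))),
      shadowThreshold = as.numeric(x$shadow_threshold),
      nIterations = as.integer(x$n_iterations),
      percentile = as.numeric(x$percentile), seed = as.integer(x$seed))
}
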