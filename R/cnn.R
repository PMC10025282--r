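# Compact 1D convolutional network for end-to-end multichannel
# classification, written directly on R matrix algebra: three blocks of
# (convolution -> ReLU -> dropout), a per-sample normalization of the
# flattened representation, two (linear -> ReLU -> dropout) blocks and a
# final linear layer to the class logits. Training uses one-hot targets
# with element-wise sigmoid + binary cross-entropy and the Adam optimizer;
# the minimum-training-loss checkpoint is kept for evaluation.
#
# Batches are carried as channel x (batch * length) concatenations so every
# layer is a handful of BLAS matrix products.

#' 1D CNN hyperparameter configuration
#'
#' Defaults follow the study protocol: kernel size 7, stride 1, three
#' convolution blocks (widths 16/32/64, each followed by width-2 average
#' pooling), dropout 0.09, three linear blocks (widths 128/32/n_classes),
#' 20 epochs, training batch 64, test batch 16, learning rate 0.0004, ReLU
#' activations, sigmoid + binary cross-entropy on one-hot targets, Adam.
#'
#' @param n_classes number of output classes (>= 2).
#' @param input_len samples per channel (482 for the default protocol).
#' @param in_channels input channels (7 for the array).
#' @param conv_widths widths of the three convolution blocks.
#' @param kernel odd kernel size.
#' @param stride convolution stride (1 supported).
#' @param pool_size average-pooling width after each convolution block
#'   (1 disables pooling).
#' @param linear_widths widths of the two hidden linear blocks.
#' @param dropout dropout probability in [0, 1).
#' @param epochs training epochs.
#' @param batch_train,batch_test batch sizes.
#' @param lr Adam learning rate.
#' @param checkpoint_on \code{"train"} (default) or \code{"test"} loss.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return validated configuration list.
#' @export
cnnConfig <- function(n_classes, input_len = 482L, in_channels = 7L,
                      conv_widths = c(16L, 32L, 64L), kernel = 7L,
                      stride = 1L, pool_size = 2L,
                      linear_widths = c(128L, 32L),
                      dropout = 0.09, epochs = 20L, batch_train = 64L,
                      batch_test = 16L, lr = 4e-4,
                      checkpoint_on = c("train", "test"), seed = 1L) {
  checkpoint_on <- match.arg(checkpoint_on)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (kernel %% 2L == 0L) stop("kernel size must be odd")
  if (stride != 1L) stop("only stride 1 is supported")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (length(conv_widths) != 3L || length(linear_widths) != 2L)
    stop("three convolution widths and two hidden linear widths required")
  if (pool_size < 1L) stop("pool_size must be >= 1")
  lens <- .cnnLengths(input_len, kernel, pool_size)
  if (any(lens$conv < 1L) || lens$out < 1L)
    stop("input too short for three stacked kernels")
  list(n_classes = as.integer(n_classes), input_len = as.integer(input_len),
       in_channels = as.integer(in_channels),
       conv_widths = as.integer(conv_widths), kernel = as.integer(kernel),
       stride = as.integer(stride), pool_size = as.integer(pool_size),
       linear_widths = as.integer(linear_widths), dropout = dropout,
       epochs = as.integer(epochs), batch_train = as.integer(batch_train),
       batch_test = as.integer(batch_test), lr = lr,
       checkpoint_on = checkpoint_on, seed = as.integer(seed))
}

# per-layer series lengths through the conv/pool chain
.cnnLengths <- function(input_len, kernel, pool_size) {
  Tcur <- as.integer(input_len)
  conv <- integer(3L); pool <- integer(3L)
  for (l in 1:3) {
    conv[l] <- Tcur - as.integer(kernel) + 1L
    pool[l] <- if (pool_size > 1L) conv[l] %/% as.integer(pool_size)
      else conv[l]
    Tcur <- pool[l]
  }
  list(conv = conv, pool = pool, out = Tcur)
}

#' Build an untrained 1D CNN
#'
#' He-initialized parameters drawn deterministically from the configured
#' seed.
#'
#' @param config a \code{\link{cnnConfig}}.
#' @return model list (parameters + config), class \code{"cnnModel"}.
#' @export
buildCNN <- function(config) {
  set.seed(config$seed)
  k <- config$kernel
  cw <- c(config$in_channels, config$conv_widths)
  params <- list()
  for (l in 1:3) {
    fan_in <- cw[l] * k
    params[[paste0("Wc", l)]] <- array(
      stats::rnorm(cw[l + 1L] * cw[l] * k, 0, sqrt(2 / fan_in)),
      dim = c(cw[l + 1L], cw[l], k))
    params[[paste0("bc", l)]] <- numeric(cw[l + 1L])
  }
  lens <- .cnnLengths(config$input_len, k, config$pool_size)
  t_out <- lens$out
  flat <- config$conv_widths[3L] * t_out
  lw <- c(flat, config$linear_widths, config$n_classes)
  for (l in 1:3) {
    params[[paste0("Wl", l)]] <- matrix(
      stats::rnorm(lw[l + 1L] * lw[l], 0, sqrt(2 / lw[l])),
      lw[l + 1L], lw[l])
    params[[paste0("bl", l)]] <- numeric(lw[l + 1L])
  }
  structure(list(params = params, config = config, flat = flat,
                 t_out = t_out, lens = lens),
            class = "cnnModel")
}

# --- layer primitives on batch-concatenated matrices -----------------------

# X: C x (B*Tin); W: O x C x K. Returns O x (B*Tout) with Tout = Tin-K+1.
# Thin wrappers over the compiled kernels in src/conv1d.cpp.
.convF <- function(X, W, b, B, Tin) .conv1dForward(X, W, b, B, Tin)

.convB <- function(dY, X, W, B, Tin) {
  out <- .conv1dBackward(dY, X, W, B, Tin)
  out$db <- as.numeric(out$db)
  out
}

.dropMask <- function(dm, p) {
  if (p <= 0) return(NULL)
  (matrix(stats::runif(prod(dm)), dm[1L], dm[2L]) >= p) / (1 - p)
}

# Average pooling over per-sample blocks of a batch-concatenated matrix.
.poolBase <- function(Tc, Tp, p, B) {
  as.vector(outer((seq_len(Tp) - 1L) * p + 1L, (seq_len(B) - 1L) * Tc, "+"))
}

.poolF <- function(A, Tc, p, B) {
  Tp <- Tc %/% p
  base <- .poolBase(Tc, Tp, p, B)
  P <- A[, base, drop = FALSE]
  for (o in seq_len(p - 1L)) P <- P + A[, base + o, drop = FALSE]
  P / p
}

.poolB <- function(dP, Tc, p, B, n_in_cols) {
  Tp <- Tc %/% p
  base <- .poolBase(Tc, Tp, p, B)
  dA <- matrix(0, nrow(dP), n_in_cols)
  for (o in 0:(p - 1L)) dA[, base + o] <- dP / p
  dA
}

# Forward pass. Xcat: C x (B*T). Returns logits (K x B) and the cache
# needed for the backward pass.
.cnnForward <- function(model, Xcat, B, train = FALSE) {
  cf <- model$config; pr <- model$params
  p <- if (train) cf$dropout else 0
  Tin <- cf$input_len
  pw <- cf$pool_size
  cache <- list(X0 = Xcat, Tin = c(Tin, 0L, 0L), B = B)
  A <- Xcat
  for (l in 1:3) {
    cache$Tin[l] <- Tin
    Z <- .convF(A, pr[[paste0("Wc", l)]], pr[[paste0("bc", l)]], B, Tin)
    # fused ReLU + inverted-dropout mask: one multiply forward, one backward
    M <- .dropMask(dim(Z), p)
    M <- if (is.null(M)) (Z > 0) else (Z > 0) * M
    cache[[paste0("Ain", l)]] <- A
    cache[[paste0("M", l)]] <- M
    A <- Z * M
    Tc <- Tin - cf$kernel + 1L
    if (pw > 1L) {
      cache[[paste0("npool", l)]] <- ncol(A)
      A <- .poolF(A, Tc, pw, B)
      Tin <- Tc %/% pw
    } else Tin <- Tc
  }
  V <- A
  dim(V) <- c(model$flat, B)
  mu <- colMeans(V)
  Vc <- V - rep(mu, each = model$flat)
  sig <- sqrt(colMeans(Vc^2) + 1e-5)
  Vn <- Vc / rep(sig, each = model$flat)
  cache$Vn <- Vn; cache$sig <- sig
  H <- Vn
  for (l in 1:2) {
    Z <- pr[[paste0("Wl", l)]] %*% H + pr[[paste0("bl", l)]]
    M <- .dropMask(dim(Z), p)
    M <- if (is.null(M)) (Z > 0) else (Z > 0) * M
    cache[[paste0("Hin", l)]] <- H
    cache[[paste0("Ml", l)]] <- M
    H <- Z * M
  }
  cache$Hin3 <- H
  logits <- pr$Wl3 %*% H + pr$bl3
  list(logits = logits, cache = cache)
}

# Backward pass from dLogits (K x B); returns gradient list matching params.
.cnnBackward <- function(model, cache, dLogits) {
  pr <- model$params; cf <- model$config
  g <- list()
  g$Wl3 <- tcrossprod(dLogits, cache$Hin3)
  g$bl3 <- rowSums(dLogits)
  dH <- crossprod(pr$Wl3, dLogits)
  for (l in 2:1) {
    dZ <- dH * cache[[paste0("Ml", l)]]
    g[[paste0("Wl", l)]] <- tcrossprod(dZ, cache[[paste0("Hin", l)]])
    g[[paste0("bl", l)]] <- rowSums(dZ)
    dH <- crossprod(pr[[paste0("Wl", l)]], dZ)
  }
  # layer-norm backward: dV = (dVn - mean(dVn) - Vn * mean(dVn * Vn)) / sig
  Vn <- cache$Vn
  nfl <- nrow(dH)
  m1 <- colMeans(dH)
  m2 <- colMeans(dH * Vn)
  dV <- (dH - rep(m1, each = nfl) - Vn * rep(m2, each = nfl)) /
    rep(cache$sig, each = nfl)
  B <- cache$B
  t3 <- model$t_out
  dim(dV) <- c(cf$conv_widths[3L], B * t3)
  dA <- dV
  pw <- cf$pool_size
  for (l in 3:1) {
    if (pw > 1L) {
      Tc <- cache$Tin[l] - cf$kernel + 1L
      dA <- .poolB(dA, Tc, pw, B, cache[[paste0("npool", l)]])
    }
    dZ <- dA * cache[[paste0("M", l)]]
    cb <- .convB(dZ, cache[[paste0("Ain", l)]],
                 model$params[[paste0("Wc", l)]], B, cache$Tin[l])
    g[[paste0("Wc", l)]] <- cb$dW
    g[[paste0("bc", l)]] <- cb$db
    dA <- cb$dX
  }
  g
}

.bceLoss <- function(logits, onehot) {
  P <- 1 / (1 + exp(-logits))
  eps <- 1e-12
  loss <- -mean(onehot * log(P + eps) + (1 - onehot) * log(1 - P + eps))
  list(loss = loss, dLogits = (P - onehot) / length(P))
}

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# records (C x T x N array) -> concatenated C x (N*T) matrix
.catRecords <- function(arr, idx) {
  matrix(arr[, , idx, drop = FALSE],
         nrow = dim(arr)[1L], ncol = dim(arr)[2L] * length(idx))
}

#' Train a 1D CNN
#'
#' Mini-batch Adam optimization of the sigmoid binary cross-entropy on
#' one-hot targets for the configured number of epochs. The parameters at
#' the minimum-loss epoch (training loss by default) are kept as the
#' evaluation checkpoint. Fully deterministic under the configured seed.
#'
#' @param model an untrained model from \code{\link{buildCNN}}.
#' @param x numeric array \code{channels x length x records} of normalized
#'   (unit-height) series.
#' @param y class labels of the training records.
#' @param x_test,y_test optional held-out set used only to record the test
#'   loss curve (and for checkpointing when configured).
#' @return trained model: parameters, checkpoint, per-epoch loss curves.
#' @export
trainCNN <- function(model, x, y, x_test = NULL, y_test = NULL) {
  cf <- model$config
  N <- dim(x)[3L]
  if (N == 0L) stop("empty training set")
  if (dim(x)[2L] != cf$input_len)
    stop("record length does not match the configured input length")
  y <- factor(y)
  lev <- levels(y)
  if (length(lev) != cf$n_classes)
    stop("label classes do not match n_classes")
  onehot <- matrix(0, cf$n_classes, N)
  onehot[cbind(as.integer(y), seq_len(N))] <- 1
  test_oh <- NULL
  if (!is.null(x_test)) {
    yt <- factor(y_test, levels = lev)
    test_oh <- matrix(0, cf$n_classes, dim(x_test)[3L])
    test_oh[cbind(as.integer(yt), seq_len(dim(x_test)[3L]))] <- 1
  }
  set.seed(deriveSeed(cf$seed, 9001L))
  opt <- .adamInit(model$params)
  loss_train <- numeric(cf$epochs)
  loss_test <- rep(NA_real_, cf$epochs)
  best <- Inf; best_params <- model$params; best_epoch <- 0L
  for (ep in seq_len(cf$epochs)) {
    perm <- sample.int(N)
    starts <- seq(1L, N, by = cf$batch_train)
    batch_losses <- numeric(0); batch_sizes <- integer(0)
    for (s in starts) {
      idx <- perm[s:min(s + cf$batch_train - 1L, N)]
      B <- length(idx)
      Xb <- .catRecords(x, idx)
      fw <- .cnnForward(model, Xb, B, train = TRUE)
      ls <- .bceLoss(fw$logits, onehot[, idx, drop = FALSE])
      g <- .cnnBackward(model, fw$cache, ls$dLogits)
      st <- .adamStep(model$params, g, opt, cf$lr)
      model$params <- st$params; opt <- st$state
      batch_losses <- c(batch_losses, ls$loss)
      batch_sizes <- c(batch_sizes, B)
    }
    loss_train[ep] <- sum(batch_losses * batch_sizes) / sum(batch_sizes)
    if (!is.null(test_oh)) {
      Nt <- dim(x_test)[3L]
      fw <- .cnnForward(model, .catRecords(x_test, seq_len(Nt)), Nt,
                        train = FALSE)
      loss_test[ep] <- .bceLoss(fw$logits, test_oh)$loss
    }
    mon <- if (cf$checkpoint_on == "test" && !is.null(test_oh))
      loss_test[ep] else loss_train[ep]
    if (mon < best) {
      best <- mon; best_params <- model$params; best_epoch <- ep
    }
  }
  model$checkpoint <- best_params
  model$best_epoch <- best_epoch
  model$loss_train <- loss_train
  model$loss_test <- loss_test
  model$levels <- lev
  model$trained <- TRUE
  model
}

#' Predict classes with a trained CNN
#'
#' Inference runs the minimum-loss checkpoint with dropout disabled.
#' Probabilities are element-wise sigmoids of the logits; the predicted
#' class is the position with probability >= 0.5. When zero or several
#' positions qualify, the maximum-probability position is taken (ties break
#' to the lowest index) and the record is flagged.
#'
#' @param model a trained model from \code{\link{trainCNN}}.
#' @param x array \code{channels x length x records} or a single
#'   channels-by-length matrix, normalized like the training data.
#' @return list: \code{class} (character), \code{prob} (records x classes),
#'   \code{flagged} (logical).
#' @export
predictCNN <- function(model, x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  cf <- model$config
  if (dim(x)[1L] != cf$in_channels || dim(x)[2L] != cf$input_len)
    stop("input shape does not match the model configuration")
  use <- model
  if (!is.null(model$checkpoint)) use$params <- model$checkpoint
  N <- dim(x)[3L]
  probs <- matrix(NA_real_, N, cf$n_classes)
  starts <- seq(1L, N, by = cf$batch_test)
  for (s in starts) {
    idx <- s:min(s + cf$batch_test - 1L, N)
    fw <- .cnnForward(use, .catRecords(x, idx), length(idx), train = FALSE)
    probs[idx, ] <- t(1 / (1 + exp(-fw$logits)))
  }
  qual <- probs >= 0.5
  pick <- integer(N); flagged <- logical(N)
  for (i in seq_len(N)) {
    q <- which(qual[i, ])
    if (length(q) == 1L) pick[i] <- q
    else {
      pick[i] <- which.max(probs[i, ])
      flagged[i] <- TRUE
    }
  }
  lev <- model$levels %||% as.character(seq_len(cf$n_classes))
  list(class = lev[pick], prob = probs, flagged = flagged)
}

#' End-to-end CNN experiment on a sensor-array dataset
#'
#' Normalizes record heights to 1, draws a stratified 2:1 train/test split,
#' augments the training split with noise-jittered copies (test records are
#' never augmented), trains the network and evaluates the minimum-loss
#' checkpoint on the held-out third.
#'
#' @param dataset a \linkS4class{SensorArrayExperiment}.
#' @param cnn list of \code{\link{cnnConfig}} overrides.
#' @param augment list(n_copies, noise_sd) for training augmentation.
#' @param split_seed seed of the stratified split.
#' @param seed training/initialization seed.
#' @return a \linkS4class{ClassificationReport} (single-iteration; details
#'   carry the loss curves and checkpoint epoch).
#' @export
runCNNExperiment <- function(dataset, cnn = list(),
                             augment = list(n_copies = 30L, noise_sd = 0.02),
                             split_seed = 1L, seed = 1L) {
  stopifnot(is(dataset, "SensorArrayExperiment"))
  norm <- normalizeHeight(dataset)
  y <- factor(classLabels(norm))
  sp <- .stratifiedSplit(y, test_fraction = 1/3, seed = split_seed)
  train <- norm[, sp$train]
  test <- norm[, sp$test]
  train <- augmentNoise(train, n_copies = augment$n_copies %||% 30L,
                        noise_sd = augment$noise_sd %||% 0.02,
                        seed = deriveSeed(seed, 31L))
  cfg <- do.call(cnnConfig, utils::modifyList(
    list(n_classes = nlevels(y), input_len = nTimepoints(norm),
         in_channels = nSensors(norm), seed = seed), cnn))
  model <- buildCNN(cfg)
  xtr <- responseArray(train)
  xte <- responseArray(test)
  model <- trainCNN(model, xtr, classLabels(train), xte, classLabels(test))
  pred <- predictCNN(model, xte)
  met <- computeMetrics(classLabels(test), pred$class, levels = levels(y))
  new("ClassificationReport",
      meanAccuracy = met$accuracy, iterAccuracy = met$accuracy,
      confusion = met$confusion, perClass = met$per_class,
      nSelected = NA_real_, compressionRatio = NA_real_,
      details = list(classifier = "cnn", split_seed = split_seed,
                     seed = seed, best_epoch = model$best_epoch,
                     loss_train = model$loss_train,
                     loss_test = model$loss_test,
                     flagged = sum(pred$flagged),
                     n_train = length(sp$train) *
                       (1L + (augment$n_copies %||% 30L)),
                     n_test = length(sp$test),
                     cnn = cfg))
}
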