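test_that("the forward pass honors the shape contract", {
  cfg <- tinyCnn(n_classes = 3L)
  model <- buildCNN(cfg)
  x <- array(rnorm(7 * 80), dim = c(7, 80, 1))
  out <- predictCNN(model, x)
  expect_equal(dim(out$prob), c(1L, 3L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  expect_error(predictCNN(model, array(0, dim = c(7, 40, 1))), "shape")
  expect_error(cnnConfig(n_classes = 3L, input_len = 15L, kernel = 7L),
               "too short")
  expect_error(cnnConfig(n_classes = 3L, kernel = 6L), "odd")
  expect_error(cnnConfig(n_classes = 1L), "n_classes")
})

test_that("zeroed parameters give 0.5 probabilities and the tie rule fires", {
  cfg <- tinyCnn(n_classes = 3L)
  model <- buildCNN(cfg)
  model$params <- lapply(model$params, function(p) p * 0)
  out <- predictCNN(model, array(0, dim = c(7, 80, 2)))
  expect_equal(unname(out$prob), matrix(0.5, 2, 3))
  # all probabilities tie at 0.5: lowest index wins and the event is flagged
  expect_equal(out$class, c("1", "1"))
  expect_true(all(out$flagged))
  # biased final layer dominates: logits (-10, -10, +10)
  model$params$bl3 <- c(-10, -10, 10)
  out2 <- predictCNN(model, array(rnorm(7 * 80 * 2), dim = c(7, 80, 2)))
  expect_equal(out2$class, c("3", "3"))
  expect_false(any(out2$flagged))
  expect_equal(out2$prob[, 3], c(1, 1), tolerance = 1e-4)
})

test_that("inference is deterministic (dropout disabled)", {
  model <- buildCNN(tinyCnn(n_classes = 2L))
  x <- array(rnorm(7 * 80 * 3), dim = c(7, 80, 3))
  p1 <- predictCNN(model, x)$prob
  p2 <- predictCNN(model, x)$prob
  expect_identical(p1, p2)
  # identical records get identical probabilities within one batch
  x[, , 2] <- x[, , 1]
  p <- predictCNN(model, x)$prob
  expect_equal(p[1, ], p[2, ])
})

test_that("a zero learning rate leaves parameters untouched", {
  ts <- tinySeriesSet()
  cfg <- tinyCnn(n_classes = 2L, lr = 0, epochs = 3L, dropout = 0)
  model <- buildCNN(cfg)
  before <- model$params
  trained <- trainCNN(model, ts$x, ts$y)
  expect_equal(trained$params, before)
  expect_equal(diff(range(trained$loss_train)), 0, tolerance = 1e-12)
})

test_that("training reduces the loss and the checkpoint is the loss minimum", {
  ts <- tinySeriesSet()
  cfg <- tinyCnn(n_classes = 2L, lr = 3e-3, epochs = 8L, seed = 2L)
  trained <- trainCNN(buildCNN(cfg), ts$x, ts$y)
  expect_lt(trained$loss_train[8], trained$loss_train[1])
  expect_equal(trained$best_epoch, which.min(trained$loss_train))
  pred <- predictCNN(trained, ts$x)
  expect_gte(mean(pred$class == ts$y), 0.9)
  expect_error(trainCNN(buildCNN(cfg), ts$x[, , 0, drop = FALSE],
                        character(0)), "empty")
})

test_that("seeded training is bit-reproducible", {
  ts <- tinySeriesSet()
  cfg <- tinyCnn(n_classes = 2L, lr = 1e-3, epochs = 3L, seed = 5L)
  t1 <- trainCNN(buildCNN(cfg), ts$x, ts$y)
  t2 <- trainCNN(buildCNN(cfg), ts$x, ts$y)
  expect_identical(t1$loss_train, t2$loss_train)
  expect_identical(t1$params, t2$params)
})

test_that("the end-to-end CNN experiment reports a full confusion matrix", {
  cfg <- smallConfig(seed = 21L, noise = noiseConfig())
  ds <- simulateExperiment(cfg)
  rep <- runCNNExperiment(ds,
    cnn = list(conv_widths = c(4L, 8L, 8L), linear_widths = c(16L, 8L),
               epochs = 6L, lr = 3e-3),
    augment = list(n_copies = 4L, noise_sd = 0.02),
    split_seed = 2L, seed = 3L)
  expect_s4_class(rep, "ClassificationReport")
  expect_equal(dim(confusionMatrix(rep)), c(3L, 3L))
  expect_equal(sum(confusionMatrix(rep)), 3L)   # 1/3 of 9 records
  expect_length(rep@details$loss_train, 6L)
  expect_true(all(is.finite(rep@details$loss_test)))
})
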