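test_that("linearly separable clouds are fit perfectly", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 0, 0.3), 20),
             matrix(rnorm(40, 4, 0.3), 20))
  colnames(X) <- c("u", "v")
  y <- rep(c("a", "b"), each = 20)
  fit <- fitSvm(X, y, seed = 1)
  expect_equal(mean(as.character(predict(fit$model, X)) == y), 1)
  expect_error(fitSvm(X, rep("a", 40)), "2 classes")
})

test_that("the majority-class dummy sits at chance on balanced classes", {
  pb <- plantedProblem(n = 90L, p_inf = 3L, p_noise = 5L, seed = 2L)
  y3 <- rep(c("a", "b", "c"), each = 30L)
  rep <- mccvEvaluate(pb$X, y3, select = FALSE, classifier = "majority",
                      n_iterations = 20L, seed = 3)
  expect_equal(accuracy(rep), 100 / 3, tolerance = 0.02)
})

test_that("MCCV reports are reproducible and structurally consistent", {
  pb <- plantedProblem(n = 60L, p_inf = 3L, p_noise = 9L, seed = 4L)
  r1 <- mccvEvaluate(pb$X, pb$y, select = FALSE, n_iterations = 5L, seed = 6)
  r2 <- mccvEvaluate(pb$X, pb$y, select = FALSE, n_iterations = 5L, seed = 6)
  expect_identical(r1@iterAccuracy, r2@iterAccuracy)
  expect_identical(r1@confusion, r2@confusion)
  # confusion totals: per-iteration test size x iterations
  expect_equal(sum(r1@confusion), 5L * 20L)
  expect_equal(r1@meanAccuracy, mean(r1@iterAccuracy))
  # accuracy equals the confusion-trace ratio when all iterations share it
  expect_true(r1@meanAccuracy >= 0 && r1@meanAccuracy <= 100)
})

test_that("the scaler is fit on the training split only", {
  Xtr <- matrix(rnorm(50), 10)
  Xte <- matrix(rnorm(50, 100, 5), 10)   # wildly shifted test block
  std <- vaporMix:::.standardizeTrainTest(Xtr, Xte)
  expect_equal(std$center, colMeans(Xtr))
  expect_equal(unname(colMeans(std$train)), rep(0, 5), tolerance = 1e-10)
  # test rows influence nothing
  std2 <- vaporMix:::.standardizeTrainTest(Xtr, Xte + 1000)
  expect_identical(std$center, std2$center)
  expect_identical(std$scale, std2$scale)
  expect_identical(std$train, std2$train)
})

test_that("stratified splits keep every class in both partitions", {
  y <- rep(c("a", "b", "c"), times = c(9L, 9L, 9L))
  for (s in 1:20) {
    sp <- vaporMix:::.stratifiedSplit(y, 1 / 3, seed = s)
    expect_setequal(sort(unique(y[sp$train])), c("a", "b", "c"))
    expect_setequal(sort(unique(y[sp$test])), c("a", "b", "c"))
    expect_equal(length(sp$test), 9L)
    expect_length(intersect(sp$train, sp$test), 0L)
  }
  expect_error(vaporMix:::.stratifiedSplit(c("a", "b"), 1.2), "test_fraction")
})

test_that("paired comparison shares splits and favors selection under noise dilution", {
  pb <- plantedProblem(n = 60L, p_inf = 5L, p_noise = 45L, shift = 1.2,
                       seed = 8L)
  cmp <- compareSelection(pb$X, pb$y, n_iterations = 6L, seed = 12,
                          boruta = list(max_iter = 30L))
  expect_length(cmp$paired_diff, 6L)
  expect_equal(cmp$paired_diff,
               cmp$with@iterAccuracy - cmp$without@iterAccuracy)
  # both arms score the same records (shared split seeds)
  expect_equal(sum(cmp$with@confusion), sum(cmp$without@confusion))
  expect_true(all(rowSums(cmp$with@confusion) ==
                    rowSums(cmp$without@confusion)))
  # selection reports its trace
  expect_true(all(is.finite(cmp$with@nSelected)))
  expect_true(is.finite(cmp$with@compressionRatio))
  expect_true(is.na(cmp$without@compressionRatio))
})
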