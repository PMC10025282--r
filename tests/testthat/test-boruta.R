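test_that("a perfectly informative feature is confirmed, flat features rejected", {
  set.seed(3)
  n <- 120L
  y <- rep(c("a", "b"), each = n / 2L)
  X <- cbind(label_copy = as.numeric(factor(y)),
             matrix(rnorm(n * 50L), n,
                    dimnames = list(NULL, paste0("noise", 1:50))),
             flat1 = rep(1, n), flat2 = rep(0, n))
  st <- runBoruta(X, y, percentile = 100, seed = 2)
  s <- featureStatus(st)
  expect_equal(unname(s["label_copy"]), "confirmed")
  expect_equal(unname(s["flat1"]), "rejected")
  expect_equal(unname(s["flat2"]), "rejected")
  expect_lt(sum(s[paste0("noise", 1:50)] == "confirmed"), 3L)
})

test_that("planted informative features are recovered, noise is screened out", {
  pb <- plantedProblem(n = 120L, p_inf = 5L, p_noise = 20L, seed = 7L)
  st <- runBoruta(pb$X, pb$y, seed = 5)
  s <- featureStatus(st)
  expect_gte(sum(s[pb$informative] == "confirmed"), 4L)
  expect_lte(sum(s[pb$noise] == "confirmed"), 2L)
})

test_that("selection is deterministic under the seed", {
  pb <- plantedProblem(n = 80L, p_inf = 4L, p_noise = 12L, seed = 1L)
  s1 <- runBoruta(pb$X, pb$y, max_iter = 25L, seed = 9)
  s2 <- runBoruta(pb$X, pb$y, max_iter = 25L, seed = 9)
  expect_identical(featureStatus(s1), featureStatus(s2))
  expect_identical(s1@hits, s2@hits)
  expect_identical(s1@zHistory, s2@zHistory)
})

test_that("percentile 100 applies the strict maximum-shadow rule", {
  pb <- plantedProblem(n = 80L, p_inf = 4L, p_noise = 12L, seed = 2L)
  s100 <- runBoruta(pb$X, pb$y, max_iter = 1L, percentile = 100, seed = 4)
  s80 <- runBoruta(pb$X, pb$y, max_iter = 1L, percentile = 80, seed = 4)
  # same forests (same seed), stricter threshold: fewer or equal hits
  expect_true(all(s100@hits <= s80@hits))
  expect_gte(s100@shadowThreshold[1], s80@shadowThreshold[1])
  # strict-max rule: hits are exactly the features whose Z beats every shadow
  beats_max <- s100@zHistory[1, ] > s100@shadowThreshold[1]
  expect_identical(unname(s100@hits == 1L), unname(beats_max))
})

test_that("added pure-noise columns do not disturb confirmed originals", {
  pb <- plantedProblem(n = 100L, p_inf = 5L, p_noise = 10L, seed = 3L)
  agree <- vapply(1:5, function(sd) {
    base <- featureStatus(runBoruta(pb$X, pb$y, seed = sd))
    set.seed(1000L + sd)
    extra <- matrix(rnorm(100L * 15L), 100L,
                    dimnames = list(NULL, paste0("extra", 1:15)))
    aug <- featureStatus(runBoruta(cbind(pb$X, extra), pb$y, seed = sd))
    mean((base == "confirmed") ==
           (aug[colnames(pb$X)] == "confirmed"))
  }, numeric(1))
  expect_gte(mean(agree), 0.9)
})

test_that("informative-feature recovery does not degrade with sample size", {
  rate <- vapply(c(60L, 120L, 240L), function(n) {
    mean(vapply(1:3, function(sd) {
      pb <- plantedProblem(n = n, p_inf = 5L, p_noise = 15L, seed = sd)
      s <- featureStatus(runBoruta(pb$X, pb$y, max_iter = 50L, seed = sd))
      mean(s[pb$informative] == "confirmed")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
})

test_that("column selection honors the selection state", {
  pb <- plantedProblem(n = 80L, p_inf = 4L, p_noise = 8L, seed = 5L)
  st <- runBoruta(pb$X, pb$y, seed = 3)
  red <- selectColumns(pb$X, st)
  expect_true(all(colnames(red) %in% colnames(pb$X)))
  expect_equal(ncol(red), sum(featureStatus(st) == "confirmed"))
  # all-confirmed state keeps the matrix unchanged
  allc <- st
  allc@status[] <- "confirmed"
  expect_identical(selectColumns(pb$X, allc), pb$X)
  # no confirmed features: explicit refusal, never a silent empty model
  none <- st
  none@status[] <- "rejected"
  expect_error(selectColumns(pb$X, none), "no features selected")
  expect_error(selectColumns(pb$X[, -1], st), "does not match")
})

test_that("compression ratios divide candidates by mean selected count", {
  expect_equal(compressionRatio(100, 100), 1)
  expect_equal(round(compressionRatio(720, 155.79), 2), 4.62)
  expect_equal(round(compressionRatio(720, 102.73), 2), 7.01)
  expect_equal(round(compressionRatio(720, 119.6), 2), 6.02)
  expect_error(compressionRatio(720, 0), "positive")
})

test_that("degenerate selection inputs are rejected", {
  pb <- plantedProblem(n = 40L, p_inf = 2L, p_noise = 4L, seed = 6L)
  expect_error(runBoruta(pb$X, rep("a", 40L)), "2 classes")
  expect_error(runBoruta(pb$X, pb$y, max_iter = 0L), "max_iter")
  Xbad <- pb$X; Xbad[1, 1] <- NA
  expect_error(runBoruta(Xbad, pb$y), "finite")
})
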