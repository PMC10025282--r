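test_that("a constant series passes the zero-phase filter unchanged", {
  x <- rep(3.7, 200)
  expect_lt(max(abs(zeroPhaseFilter(x) - 3.7)), 1e-8)
})

test_that("filter output equals the explicit forward-reverse composition", {
  # independent oracle: odd-reflection padding plus the filter -> reverse
  # -> filter -> reverse composition, with the steady-state initialization
  # realized independently by a long constant burn-in prefix instead of an
  # initial-state vector
  prot <- shortProtocol()
  y <- simulateResponse("A6", mixtureLabel("NH3", c(1, 0), 10, "low"),
                        protocol = prot, noise = noiseConfig(), seed = 4)
  order <- 3L; cutoff <- 0.05
  pad <- 3L * (order + 1L)
  burn <- 500L
  n <- length(y)
  bf <- signal::butter(order, 2 * cutoff, type = "low")
  pass <- function(v) {
    out <- signal::filter(bf, c(rep(v[1], burn), v))
    as.numeric(out[-(1:burn)])
  }
  xp <- c(2 * y[1] - y[(pad + 1):2], y, 2 * y[n] - y[(n - 1):(n - pad)])
  oracle <- rev(pass(rev(pass(xp))))[(pad + 1):(pad + n)]
  expect_lt(max(abs(zeroPhaseFilter(y, order, cutoff) - oracle)), 1e-8)
})

test_that("filtering introduces no phase shift", {
  # symmetric band-limited bump: the peak position is exactly preserved
  t <- 0:299
  bump <- exp(-((t - 150) / 30)^2)
  expect_equal(which.max(zeroPhaseFilter(bump)), which.max(bump))
  # kinetic curve: input/output cross-correlation peaks at lag 0
  y <- simulateResponse("T6G6", mixtureLabel("NH3", c(1, 0), 10, "low"))
  f <- zeroPhaseFilter(y)
  cc <- stats::ccf(f, y, lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # and a sinusoid keeps its phase
  s <- sin(2 * pi * 0.01 * (0:499))
  cs <- stats::ccf(zeroPhaseFilter(s), s, lag.max = 20, plot = FALSE)
  expect_equal(cs$lag[which.max(cs$acf)], 0)
})

test_that("low-pass filtering attenuates white noise", {
  reduced <- vapply(1:100, function(i) {
    set.seed(i)
    x <- stats::rnorm(300)
    stats::var(zeroPhaseFilter(x)) < stats::var(x)
  }, logical(1))
  expect_true(all(reduced))
})

test_that("degenerate filter inputs are rejected", {
  expect_error(zeroPhaseFilter(rnorm(10)), "too short")
  expect_error(zeroPhaseFilter(rnorm(100), cutoff = 0.5), "inside")
  expect_error(zeroPhaseFilter(rnorm(100), order = 0), ">= 1")
})

test_that("height normalization unifies the record maximum to 1", {
  cfg <- smallConfig(seed = 5L)
  ds <- simulateExperiment(cfg)
  nd <- normalizeHeight(ds)
  a <- assay(nd, "response")
  for (j in seq_len(ncol(a)))
    expect_equal(max(abs(a[, j])), 1)
  # scale invariance: records differing by a global factor normalize equally
  r <- getRecord(ds, 1)
  expect_equal(normalizeHeight(r), normalizeHeight(5 * r))
  # idempotence
  expect_equal(assay(normalizeHeight(nd), "response"), a)
})

test_that("degenerate records are handled explicitly by normalization", {
  z <- matrix(0, 7, 80)
  expect_warning(out <- normalizeHeight(z), "all-zero")
  expect_identical(out, z)
  bad <- matrix(1, 7, 80); bad[3, 5] <- NA
  expect_error(normalizeHeight(bad), "non-finite")
})

test_that("augmentation multiplies records and preserves class balance", {
  ds <- normalizeHeight(simulateExperiment(smallConfig(seed = 6L)))
  expect_equal(ncol(augmentNoise(ds, 0L)), ncol(ds))
  aug <- augmentNoise(ds, 4L, 0.02, seed = 9L)
  expect_equal(ncol(aug), 5L * ncol(ds))    # originals + 4 copies each
  expect_true(all(table(classLabels(aug)) == 5L * table(classLabels(ds))))
  # zero-noise copies are exact duplicates
  aug0 <- augmentNoise(ds, 2L, 0, seed = 9L)
  expect_equal(unname(assay(aug0, "response")[, ncol(ds) + 1L]),
               unname(assay(ds, "response")[, 1L]))
  # deterministic under seed
  expect_identical(assay(augmentNoise(ds, 2L, 0.05, seed = 3L), "response"),
                   assay(augmentNoise(ds, 2L, 0.05, seed = 3L), "response"))
  expect_error(augmentNoise(ds, -1L), "nonnegative")
})
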