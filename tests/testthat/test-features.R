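test_that("featurization yields exactly 120 features per sensor, 840 per record", {
  cfg <- smallConfig(seed = 2L, noise = noiseConfig())
  ds <- simulateExperiment(cfg)
  fs <- extractFeatures(filterDataset(ds))
  expect_equal(nrow(fs), 840L)
  expect_equal(ncol(fs), ncol(ds))
  expect_true(all(table(rowData(fs)$sensor_id) == 120L))
  expect_false(anyDuplicated(rowData(fs)$feature) > 0)
  expect_true(all(is.finite(assay(fs, "features"))))
  expect_error(featureLayout(mag_down = 10L), "120")
})

test_that("an all-zero record maps to the all-zero feature vector", {
  prot <- shortProtocol()
  cfg <- smallConfig(seed = 2L)
  ds <- simulateExperiment(cfg)
  a <- assay(ds, "response")
  a[, 1L] <- 0
  assay(ds, "response") <- a
  fs <- extractFeatures(ds)
  expect_true(all(assay(fs, "features")[, 1L] == 0))
})

test_that("time constants of exact exponentials are recovered within one sample", {
  t <- 0:367
  expect_equal(computeTimeConstant(10 * (1 - exp(-t / 30)), 1, "rise"), 30,
               tolerance = 1 / 30)
  expect_equal(computeTimeConstant(10 * exp(-(0:113) / 60), 1, "decay"), 60,
               tolerance = 1 / 60)
  # sign convention carries through
  expect_equal(computeTimeConstant(-10 * (1 - exp(-t / 45)), 1, "rise"), 45,
               tolerance = 1 / 45)
  expect_equal(computeTimeConstant(rep(2.5, 50), 1, "rise"), 0)
  expect_equal(computeTimeConstant(rep(2.5, 50), 1, "decay"), 0)
  expect_error(computeTimeConstant(1:3), "at least 5")
})

test_that("areas follow the trapezoid rule", {
  expect_equal(computeArea(rep(1, 100), 1), 99)
  expect_equal(computeArea(rep(0, 50), 1), 0)
  expect_equal(computeArea(seq(0, 10, length.out = 100), 1), 495)
  expect_equal(computeArea(rep(1, 100), 2), 49.5)  # %.s halves at 2 Hz
})

test_that("interval differences isolate in-window changes and telescope", {
  prot <- shortProtocol()
  sch <- intervalScheme(prot)
  expect_equal(computeDifferences(rep(4, prot$n_samples), sch), rep(0, 5))
  # step of +8 strictly inside the first reaction window
  y <- numeric(prot$n_samples)
  w1 <- sch$diff[1, ]
  y[(w1$start + 5L):prot$n_samples] <- 8
  y[(sch$diff$start[2]):prot$n_samples] <- 8  # keep flat at later windows
  d <- computeDifferences(y, sch)
  expect_equal(d, c(8, 0, 0, 0, 0))
  # contiguous reaction windows telescope to plateau - baseline
  yk <- simulateResponse("T6G6", mixtureLabel("NH3", c(1, 0), 10, "low"),
                         protocol = prot)
  dk <- computeDifferences(yk, sch)
  expect_equal(sum(dk[1:2]), yk[prot$n_injection] - yk[1])
})

test_that("derivative features obey ramp and kinetic oracles", {
  prot <- shortProtocol()
  ramp <- 0.25 * (0:(prot$n_samples - 1))
  dv <- derivativeFeatures(ramp, 1, prot$n_injection, 30L)
  expect_equal(dv$d1_max, 0.25)
  expect_equal(dv$d1_min, 0.25)
  expect_equal(dv$d2_inj_max, 0, tolerance = 1e-10)
  expect_length(dv$d1_down, 30L)
  # rising exponential: steepest ascent at injection onset
  yk <- 12 * (1 - exp(-(0:79) / 15))
  dk <- derivativeFeatures(yk, 1, 60L, 30L)
  expect_equal(which.max(diff(yk)), 1L)
  expect_equal(dk$d1_max, max(diff(yk)))
})

test_that("features are scale-equivariant in the documented families", {
  cfg <- smallConfig(seed = 8L, noise = noiseConfig())
  ds <- simulateExperiment(cfg)
  fs1 <- extractFeatures(ds)
  ds2 <- ds
  assay(ds2, "response") <- 3 * assay(ds, "response")
  fs2 <- extractFeatures(ds2)
  fam <- rowData(fs1)$family
  scaled <- fam %in% c("magnitude", "derivative", "second_derivative",
                       "difference", "area")
  expect_equal(assay(fs2, "features")[scaled, ],
               3 * assay(fs1, "features")[scaled, ])
  expect_equal(assay(fs2, "features")[!scaled, ],
               assay(fs1, "features")[!scaled, ])
})

test_that("permuting channels permutes feature blocks identically", {
  cfg <- smallConfig(seed = 9L, noise = noiseConfig())
  ds <- simulateExperiment(cfg)
  nt <- nTimepoints(ds)
  a <- assay(ds, "response")
  swap <- a
  swap[1:nt, ] <- a[(nt + 1):(2 * nt), ]       # channel 2 -> slot 1
  swap[(nt + 1):(2 * nt), ] <- a[1:nt, ]       # channel 1 -> slot 2
  ds2 <- ds
  assay(ds2, "response") <- swap
  f1 <- assay(extractFeatures(ds), "features")
  f2 <- assay(extractFeatures(ds2), "features")
  expect_equal(unname(f2[1:120, ]), unname(f1[121:240, ]))
  expect_equal(unname(f2[121:240, ]), unname(f1[1:120, ]))
  expect_equal(unname(f2[241:840, ]), unname(f1[241:840, ]))
})

test_that("low-quality channels are zeroed as whole blocks", {
  cfg <- smallConfig(seed = 10L, noise = noiseConfig())
  ds <- simulateExperiment(cfg)
  fs <- extractFeatures(filterDataset(ds))
  snr <- channelSNR(ds)
  # all channels above threshold: unchanged
  ok <- zeroLowQuality(fs, snr, threshold = 0)
  expect_equal(assay(ok, "features"), assay(fs, "features"))
  # force one channel below threshold: exactly 120 rows zeroed
  snr2 <- snr
  snr2["A6"] <- 0.1
  masked <- zeroLowQuality(fs, snr2, threshold = 3)
  expect_equal(metadata(masked)$low_quality_channels, "A6")
  a6 <- rowData(fs)$sensor_label == "A6"
  expect_equal(sum(a6), 120L)
  expect_true(all(assay(masked, "features")[a6, ] == 0))
  expect_equal(assay(masked, "features")[!a6, ],
               assay(fs, "features")[!a6, ])
})
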