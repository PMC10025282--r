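test_that("plateau calibration matches the reported reactivities", {
  # T6G6 at 10 ppm dry NH3 sits at the 15% calibration point
  y <- simulateResponse("T6G6", mixtureLabel("NH3", c(1, 0), 10, "low"))
  expect_equal(y[368], 15, tolerance = 1e-3)
  expect_length(y, 482)
  # pristine graphene calibrated to ~10% for dry NH3 and NO2
  expect_equal(simulateResponse("pristine",
    mixtureLabel("NH3", c(1, 0), 10, "low"))[368], 10, tolerance = 1e-3)
  expect_equal(abs(simulateResponse("pristine",
    mixtureLabel("NO2", c(1, 0), 10, "low"))[368]), 10, tolerance = 1e-3)
  # humid NH3 plateaus lie in the 20-32% band on every channel
  pv <- plateauVector(mixtureLabel("NH3", c(1, 0), 10, "high"))
  expect_true(all(pv >= 20 & pv <= 32))
  # humid H2S plateaus lie in the 20-40% band
  pv2 <- plateauVector(mixtureLabel("H2S", c(1, 0), 10, "high"))
  expect_true(all(pv2 >= 20 & pv2 <= 40))
})

test_that("no stimulus means no response, and plateaus grow with concentration", {
  z <- simulateResponse("A6", mixtureLabel("NH3", c(1, 0), 0, "low"))
  expect_true(all(z == 0))
  for (g in gasSpecies()$name) {
    for (ch in 1:7) {
      p <- vapply(c(2, 5, 10), function(conc) {
        abs(plateauVector(mixtureLabel(g, c(1, 0), conc, "low"))[ch])
      }, numeric(1))
      expect_true(all(diff(p) > 0),
                  info = sprintf("gas %s channel %d", g, ch))
    }
  }
})

test_that("mixture plateaus are the ratio-weighted combination of pure plateaus", {
  prot <- exposureProtocol()
  for (r in list(c(1, 1), c(1, 3), c(3, 1), c(2, 1), c(1, 2))) {
    mix <- plateauVector(mixtureLabel(c("NO2", "NH3"), r, 10, "low"))
    p1 <- plateauVector(mixtureLabel("NO2", c(1, 0), 10, "low"))
    p2 <- plateauVector(mixtureLabel("NH3", c(1, 0), 10, "low"))
    w <- r / sum(r)
    # kinetics differ per gas, so compare at the ideal plateau level:
    # the end-of-injection value is within a small kinetic completion
    # error of the convex combination
    expect_lt(max(abs(mix - (w[1] * p1 + w[2] * p2))), 0.02)
    expect_true(all(mix >= pmin(p1, p2) - 0.02 & mix <= pmax(p1, p2) + 0.02))
  }
})

test_that("experiment inventory follows the measurement protocol", {
  cfg <- presetConfig("NO2-NH3-low", seed = 3)
  ds <- simulateExperiment(cfg)
  expect_equal(ncol(ds), 27L)               # 3 ratios x 9 replicates
  expect_true(all(table(classLabels(ds)) == 9L))
  expect_equal(nTimepoints(ds), 482L)
  cfg5 <- presetConfig("NH3-H2S-high", seed = 3)
  ds5 <- simulateExperiment(cfg5)
  # 27 mixture records + 2 gases x 3 concentrations x 3 replicates
  expect_equal(ncol(ds5), 45L)
  expect_setequal(unique(classLabels(ds5)),
                  c("1:1", "1:3", "3:1", "NH3", "H2S"))
  expect_equal(sum(classLabels(ds5) == "NH3"), 9L)
})

test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- smallConfig(seed = 11L, noise = noiseConfig())
  d1 <- simulateExperiment(cfg)
  d2 <- simulateExperiment(cfg)
  expect_identical(assay(d1, "response"), assay(d2, "response"))
  expect_identical(as.data.frame(colData(d1)), as.data.frame(colData(d2)))
  d3 <- simulateExperiment(smallConfig(seed = 12L, noise = noiseConfig()))
  expect_false(identical(assay(d1, "response"), assay(d3, "response")))
})

test_that("noiseless class plateau vectors are pairwise distinct", {
  for (nm in presetNames()) {
    cfg <- presetConfig(nm)
    hums <- if (cfg$humidity == "shuffled") c("low", "high") else cfg$humidity
    for (h in hums) {
      labs <- lapply(cfg$ratios, function(r)
        mixtureLabel(cfg$gases, r, 10, h))
      if (cfg$class_schema == "ratios+pure")
        labs <- c(labs, lapply(cfg$gases, function(g)
          mixtureLabel(g, c(1, 0), 10, h)))
      pv <- vapply(labs, plateauVector, numeric(7))
      d <- as.matrix(stats::dist(t(pv)))
      expect_true(all(d[upper.tri(d)] > 0.5), info = paste(nm, h))
    }
  }
})

test_that("invalid labels and configurations are rejected", {
  expect_error(mixtureLabel("CO2", c(1, 0), 10, "low"), "unknown gas")
  expect_error(mixtureLabel("NH3", c(0, 0), 10, "low"), "not both zero")
  expect_error(exposureProtocol(sample_hz = 0), "positive")
  expect_error(exposureProtocol(10, 5, 1), "at least 50")
  expect_error(experimentConfig(ratios = list()), "empty class set")
  expect_error(experimentConfig(gases = c("NH3", "XYZ")), "pair")
  amp <- defaultAmplitudeTable()
  amp["A6", "NH3", "low"] <- NA
  expect_error(simulateResponse("A6", mixtureLabel("NH3", c(1, 0), 10, "low"),
                                amplitude_table = amp), "does not cover")
})
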