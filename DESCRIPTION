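Package: vaporMix
Title: Discrimination of Mixed Chemical Vapors from Gas-Sensor-Array Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multichannel chemiresistive gas-sensor-array
    response curves and discriminating the composition of mixed chemical
    vapors (NH3, NO, NO2, H2S at varying mixing ratios, under low- and
    high-humidity conditions). Provides a calibrated synthetic response
    generator built on first-order adsorption/desorption kinetics, zero-phase
    forward-backward IIR filtering, a 120-feature-per-channel curve
    featurization (840 features for a 7-sensor array), all-relevant feature
    selection with shadow features and random-forest importance, Monte-Carlo
    cross-validated support-vector-machine classification, and a compact 1D
    convolutional neural network for end-to-end multichannel time-series
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, signal, ranger, e1071,
    jsonlite, data.table, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
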