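Package: gaitwrf
Title: Plantar-Pressure Gait Recognition with Wavelet Denoising and
    Weighted Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gait-pattern recognition from plantar-pressure
    recordings made with a 6x6 flexible hydrogel sensor array. Provides a
    physical and calibration model of the piezoresistive sensing units
    (quadratic conductance-to-pressure calibration and its inversion), a
    synthetic generator of labelled plantar-pressure sequences for four
    gait patterns with a configurable noise model, a wavelet-threshold
    denoising chain with max normalization, amplitude/skewness/kurtosis
    feature extraction, and a weighted random forest classifier in which
    each tree votes with a weight derived from its out-of-bag F-measure.
    Includes confusion-matrix evaluation, Pearson covariate analysis, and
    a seed-matched harness comparing weighted against uniform-vote forests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
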