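Package: pulsegrip
Title: Pulsatile Grip-Force Simulation and Vessel Classification with
    Fiber Bragg Grating Tactile Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsatile gripping-force signals from parameterized
    vessel and tissue models, converts them through a fiber Bragg grating
    (FBG) force-sensor model, preprocesses them with wavelet soft-threshold
    denoising, Z-score normalization and moving-average smoothing, extracts
    the peak clamping force fluctuation (PCFF) statistic and pulse
    frequency, runs the standard group-comparison battery (t-test,
    Mann-Whitney U, Kruskal-Wallis), and classifies vessel condition with a
    dual-path one-dimensional CNN-LSTM network trained by stochastic
    gradient descent with Nesterov momentum and a cosine-annealing-with-
    restarts learning-rate schedule. All stages are seeded and reproducible
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
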