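Package: spikecoder
Title: Behavioral Simulation of a Dual-Gated Transistor Spike Encoder and
    Spiking Neural Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a biomimetic neural encoder built around a dual-gated
    field-effect transistor with a stochastic sampling gate. Analog stimulus
    voltages (or LED illuminance passed through a photodiode front-end) are
    converted into binary spike trains under rate-based, spike-count-based and
    time-to-first-spike encoding algorithms. Includes a compact subthreshold
    device model with spiking-threshold extraction, closed-form Gaussian-CDF
    encoding transfer functions, per-spike energy accounting, an image-to-spike
    pipeline with reconstruction and correlation tracking, and an ANN-to-SNN
    conversion pipeline (threshold balancing plus integrate-and-fire inference)
    for classifying spike-encoded images. Synthetic fixture generators
    (gradients, checkerboards, disk phantoms, blob digits) make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
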