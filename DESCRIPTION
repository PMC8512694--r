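Package: ecgfusion
Title: Multi-Horizon Driver-State Forecasting from Single-Lead ECG with
    Evolutionary Model Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts a driver's physiological state (stress level or
    drowsiness stage, three classes) 1-60 seconds ahead from single-lead
    ECG. Implements QRS/R-wave detection and beat segmentation via a
    Pan-Tompkins-style filter chain, pairwise-beat convolution and
    cross-correlation features, from-equation Elman (power-sigmoid) RNN,
    GRU and LSTM multi-horizon classifiers trained with analytic
    gradients, and an NSGA-III many-objective optimizer that fuses the
    three recurrent models into a single per-horizon weighted ensemble
    maximizing overall and per-class accuracy. Ships a synthetic ECG
    generator with semi-Markov class dynamics so the whole pipeline is
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
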