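Package: driftgate
Title: Drift-Gated Incremental Classification of Time Series
Version: 0.1.0
Authors@R:
    person("driftgate", "maintainers", email = "maintainers@driftgate.dev",
           role = c("aut", "cre"))
Description: Incremental-learning pipeline for classifying streams of
    fixed-length time series (biosignals such as plant surface potentials or
    ECG beats) whose distribution drifts over time. A Kullback-Leibler drift
    score computed on per-feature equal-interval histograms compares each new
    update window against the training data; when the score crosses a
    threshold, a lightweight extreme-learning-machine autoregressive
    preprocessor rewrites the window toward training-data dynamics so that a
    fixed, pretrained stacked LSTM classifier can keep serving without
    retraining. Includes window generation in feature- and sample-update
    modes, threshold calibration by bootstrap, one-vs-rest evaluation metrics
    (accuracy, sensitivity, specificity, F1, rank-based AUC), and a synthetic
    generator of class-structured periodic series with controllable drift,
    noise, spikes and missing points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
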