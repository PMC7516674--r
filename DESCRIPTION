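Package: hypnohrv
Title: Hypnopompic Heart Rate Variability Analysis and Cardiovascular Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing heart rate variability (HRV) in the final hour
    of nocturnal sleep and for predicting cardiovascular-disease outcomes from
    the resulting metrics. Provides Pan-Tompkins QRS detection, RR-interval
    artifact flagging and spline correction, time-domain (SDNN, RMSSD) and
    frequency-domain (total, low- and high-frequency band power) HRV measures,
    multiscale sample entropy and tied-rank (modified) permutation entropy,
    distribution-similarity diagnostics (Lilliefors, two-sample
    Kolmogorov-Smirnov, Jensen-Shannon divergence), and an imbalance-aware,
    stratified cross-validated gradient-boosted-tree classifier with
    split-count feature importance. A synthetic-data module generates ECG
    traces, RR series with controllable oscillatory and broadband-noise
    structure, and two-group cohorts so that the entire pipeline can be
    exercised and validated without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    nortest,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
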