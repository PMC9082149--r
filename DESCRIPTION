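Package: ecgrecon
Title: Subject-Specific ECG Reconstruction from Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstructs long electrocardiogram (ECG) traces from a
    simultaneously recorded photoplethysmogram (PPG) with a subject-specific
    bidirectional LSTM sequence regressor. Provides zero-phase Chebyshev II
    band-pass filtering, Pan-Tompkins R-peak detection, two-moving-average
    systolic-peak detection, pulse-arrival-time alignment, second-based
    train/validation/test splitting and segmentation, segment stitching,
    cross-correlation lag re-alignment, and an evaluation suite (Pearson r,
    root mean square error, dynamic time warping with an anchored warping
    path). A seeded generator of paired synthetic ECG/PPG records with
    ground-truth peak annotations supports testing and benchmarking without
    access to clinical waveform databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
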