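Package: edasleep
Title: Sleep Staging and Sleep Apnoea Screening from Electrodermal Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying what a single electrodermal
    activity (EDA) channel can say about sleep. Provides a calibrated
    synthetic full-night EDA generator with ground-truth hypnograms and
    event/storm annotations; the signal-conditioning chain used for
    endosomatic EDA (rational downsampling to 35 Hz, polynomial detrending,
    Savitzky-Golay smoothing, wavelet soft-threshold denoising, FIR
    differentiation); detection of band-limited EDA events and storms; a
    77-variable per-epoch feature set; greedy correlation-based feature
    reduction; SMOTE-balanced gradient-boosted classification of sleep
    stages and obstructive sleep apnoea severity under leave-one-subject-out
    and personalized validation; and SHAP-based model interpretation.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    caret,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
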