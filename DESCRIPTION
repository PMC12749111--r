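Package: mepscore
Title: Detection and Scoring of Stimulation-Evoked Motor Potentials in
    Multi-Channel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automated detection of deep brain stimulation (DBS)-induced motor
    evoked potentials (mEP) in multi-channel surface electromyography.
    Implements pulse-triggered averaging, baseline z-scoring, subtractive
    60 Hz line-noise removal, stimulation-artifact rejection (template,
    PCA, and template-PCA hybrid), latency-windowed peak detection with
    muscle-specific windows, and aggregation of per-muscle responses into a
    single normalized mEP score quantifying internal-capsule activation.
    Ships a synthetic DBS-EMG generator with known ground truth so every
    stage of the pipeline can be exercised and evaluated without patient
    data, plus evaluation utilities (accuracy, F1 threshold sweeps,
    stimulation-duration sweeps, waveform-correlation analysis).
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
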