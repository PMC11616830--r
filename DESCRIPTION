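Package: murmurscreen
Title: Heart Murmur Screening from Phonocardiograms with a Bayesian
    Residual Network and Multimodal Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening pipeline for paediatric heart murmur detection from
    phonocardiogram recordings. Raw waveforms are turned into overlapping
    log-mel spectrogram windows, classified by a dropout-augmented residual
    network whose Monte Carlo dropout passes yield predictive mean and
    uncertainty, aggregated to patient level by arithmetic means, and fused
    with demographic and audio summary features through gradient-boosted
    trees. Includes the matching evaluation protocol (patient-grouped
    stratified cross-validation, threshold sweeps, balanced subsampling,
    zero-shot multi-site transfer) and a synthetic phonocardiogram cohort
    generator so the whole pipeline can be exercised without any data
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
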