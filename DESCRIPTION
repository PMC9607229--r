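Package: gaitEE
Title: Steady-State Energy Expenditure Estimation from Wearable Sensors in
    Slow and Exoskeleton-Assisted Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for estimating steady-state metabolic energy
    expenditure (W/kg) during slow treadmill walking, with and without
    ankle-foot exoskeleton assistance, from fused wearable-sensor channels
    (8-segment inertial magnitudes, MVC-normalized EMG sums, normalized heart
    rate, gait speed and anthropometrics). Includes a seeded synthetic
    multimodal gait-trial simulator with known ground truth; the signal
    conditioning chains (Brockway conversion of breath-by-breath gas exchange,
    confidence-interval trimmed steady-state extraction, zero-lag Butterworth
    filtering, EMG envelope and MVC normalization); leakage-safe min-max
    scaling and sliding-window dataset assembly; natively implemented 1-D
    convolutional and LSTM regressors trained with Adam; and a
    leave-one-subject-out cross-validation harness reporting MSE, RMSE, NMSE,
    Spearman correlation, Bland-Altman agreement and linear-fit R-squared,
    including the speed-by-condition error decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
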