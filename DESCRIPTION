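Package: wotrack
Title: Tracking the Levodopa Wearing-Off Phenomenon from Wearable EMG/EEG Gait Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discriminating the ON and OFF phases of
    the levodopa wearing-off phenomenon in Parkinson's disease from bilateral
    lower-limb surface electromyography (and optional electroencephalography)
    recorded during walking. Includes a calibrated synthetic walking-session
    generator, dynamic-threshold conversion of raw sEMG channels into binary
    muscle activation triggers, gait-cycle segmentation with per-stride
    muscular indexes (stride time, duty cycles, co-contraction times),
    movement-related-potential band features extracted by short-time Fourier
    analysis at each foot-strike, paired t-test feature selection, a zoo of
    shallow and small dense neural-network classifiers with a self-contained
    forward-pass engine and multiply-accumulate complexity accounting, and a
    standard binary-classification evaluation surface (confusion matrix,
    accuracy/recall/precision/F1, ROC and AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    MASS,
    e1071,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
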