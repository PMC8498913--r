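Package: mibmi
Title: Motor-Imagery EEG Simulation, Classification, and Online BMI Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sensorimotor EEG with event-related
    desynchronization/synchronization structure, implements a
    motor-imagery brain-machine-interface analysis pipeline (Butterworth
    filtering, windowing, Welch power spectral density features), three
    classifier families (a spatial-first convolutional network, a
    temporal-first convolutional network, and a cubic-kernel SVM on
    spectral features), fivefold leave-one-recording-out cross-validation,
    Wolpaw information-transfer-rate and alpha-rhythm SNR metrics, and a
    real-time sliding-window control scheme with two-agreement command
    confirmation scored against a cued VR-game schedule.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
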