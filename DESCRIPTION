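Package: affectr
Title: EEG-Based Emotion Recognition with Hjorth Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free pipeline for four-class emotion recognition
    (happy, calm, sad, scared) from 14-channel consumer-headset EEG sampled
    at 128 Hz. Provides a seedable synthetic EEG generator with
    emotion-dependent spectral structure, zero-phase band decomposition into
    the clinical delta/theta/alpha/beta bands, three feature families
    (filtered-signal vectors and per-band Hjorth parameters on 14 or 6
    channels), mutual-information feature ranking, SVM and KNN classifiers
    with stratified 10-fold cross-validation, majority-vote smoothing of
    per-epoch decisions into 15-second emotion feedback, and per-user
    profiles storing labeled training epochs and emotion-keyed treatment
    notes. All tabular results are tibbles; fitted objects support tidy()
    and glance().
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    e1071,
    caret,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
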