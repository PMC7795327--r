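Package: arsound
Title: Adventitious Respiratory Sound Classification with
    Duration-Controlled Negative Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how experimental design, in particular the
    construction of the negative ("other") class, affects automatic
    classification of adventitious respiratory sounds (wheezes and
    crackles). Provides audio and annotation input/output with
    participant-based splitting, a synthetic lung-sound corpus generator,
    Burr Type XII duration modelling, fixed-duration and variable-duration
    random event generation, spectrogram and mel-spectrogram images,
    multiscale spectral/cepstral/melodic feature extraction, minimum
    redundancy maximum relevance feature ranking, classical classifiers
    with seeded model-based hyperparameter search, a compact convolutional
    network, and an experiment runner with one-vs-all evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    e1071,
    rpart,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
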