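Package: pfeeg
Title: Personality-First Cross-Subject EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("pfeeg", "developers", email = "pfeeg@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-subject emotion recognition from
    multi-channel EEG with a personality-first training scheme. Subjects
    are clustered on Big-Five (OCEAN) personality vectors with k-means
    and one emotion model is trained per personality cluster; held-out
    subjects are routed to the nearest personality centroid. The emotion
    model is a channel-attention bidirectional LSTM operating on
    differential-entropy band features (delta, theta, low/high alpha,
    beta) of windowed EEG segments, with a learned column-stochastic
    channel weight matrix as the interpretability output. Includes a
    synthetic EEG generator with personality-clustered subjects and
    planted channel-by-band affective signal, leave-one-subject-out and
    k-fold evaluation protocols, linear SVM and gradient-boosted stump
    baselines, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
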