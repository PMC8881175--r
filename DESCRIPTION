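Package: erptrial
Title: Single-Trial ERP Detection and Estimation by Classifier Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects and estimates the amplitude and latency of event-related
    potential (ERP) components in single EEG trials. Models an ERP component
    as a Gaussian template superposed on spontaneous EEG, trains a binary
    classifier (logistic regression, multilayer perceptron, or support vector
    machine) to separate spontaneous from ERP-bearing channel-vector samples,
    and inverts the classifier's distance-to-boundary to recover per-trial
    latency (exhaustive search) and amplitude (bounded scalar minimization).
    Includes a synthetic spontaneous-EEG generator, standard preprocessing
    (FIR high-pass, linked-mastoid rereferencing, epoching, baseline
    correction), Woody adaptive-filter and SingleTrialEM reference
    estimators, and a paired-click sensory-gating analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    nnet,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
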