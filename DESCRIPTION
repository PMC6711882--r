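Package: mweeg
Title: Task-General Mind-Wandering Detection from Single-Trial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for detecting mind-wandering
    (task-unrelated thought) from epoched EEG. Implements single-trial
    event-related potential estimation by Mexican-hat wavelet template
    matching (P1, N1, P3), plateau-shaped least-squares FIR band-pass
    filtering with Hilbert-transform band power and intersite phase
    clustering (alpha and theta bands), experience-sampling probe-based
    trial labeling, and per-subject RBF support-vector-machine
    classification with random oversampling, within-task leave-one-out
    cross-validation, across-task transfer, and single-marker models.
    Includes a synthetic EEG session generator that emulates the
    probe-scheduled experimental design and the expected mental-state
    effects, so the whole pipeline runs without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
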