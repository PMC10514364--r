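Package: kcdetect
Title: Automated K-Complex Detection in Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of k-complexes in single-channel sleep EEG by classical
    machine learning. Implements sliding-window segmentation of band-pass
    filtered recordings, a 22-dimensional multi-domain feature set (time,
    spectral, and fractal/chaotic descriptors including correlation, box, and
    generalized Renyi dimensions), five feature-selection algorithms (ReliefF,
    correlation-based feature selection, exhaustive/best-first subset search
    under consistency and classifier-error measures, and INTERACT), and a
    cross-validated detection harness with linear discriminant analysis,
    linear support vector machine, and decision tree classifiers. Includes
    minimal European Data Format (EDF) input/output and a seeded synthetic
    sleep-EEG generator with ground-truth annotations so the whole pipeline is
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    e1071,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
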