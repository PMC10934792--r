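Package: mitfopt
Title: Adaptive Time-Frequency Segment Optimization for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-specific decoding of two-class motor-imagery EEG. A sparrow
    search algorithm optimizes the time window and frequency band applied to
    epoched trials, using cross-validated classification accuracy as its
    fitness; channels are then selected by mean Pearson correlation with
    voting across trials, features are extracted with a regularized common
    spatial pattern (covariance mixing and shrinkage toward scaled identity),
    and trials are classified with a radial-basis-function support vector
    machine tuned by grid search. Includes a synthetic generator of two-class
    trials with event-related desynchronization planted at a known time
    window, frequency band and channel subset, so that segment recovery,
    channel recovery and end-to-end accuracy are all testable offline, plus a
    portable binary fixture format for epoched EEG.
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
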