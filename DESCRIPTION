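Package: zonewatch
Title: Pose-Based Red-Zone Entry Monitoring and Diagnostic Accuracy
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detector-agnostic engine for monitoring entries of healthcare
    personnel into a user-defined "red zone" polygon around a patient bed,
    from per-frame human pose landmarks. Provides polygon containment
    testing, greedy nearest-centroid multi-person tracking, a debounced
    zone-entry state machine that suppresses double counting caused by
    occlusion, face-redaction geometry, a synthetic scene simulator with
    ground-truth entry labels, and diagnostic-accuracy statistics
    (sensitivity and specificity with Wald, Wilson or Clopper-Pearson
    confidence intervals, plus sample-size planning for a target interval
    half-width).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
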