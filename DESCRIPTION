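Package: arftriage
Title: Ultrasound Plus Blood-Gas Triage Algorithms for Acute Respiratory
    Failure and Their Diagnostic Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based classification of the aetiology of acute respiratory
    failure in dyspneic ICU patients into five pathophysiological categories
    (alveolar-lung, alveolar-cardiac, ventilation-with-alveolar, perfusion,
    metabolic), using either critical care ultrasonography combined with
    arterial blood gas analysis or a conventional chest-X-ray reading.
    Includes the complete agreement and diagnostic-accuracy toolkit for
    validating such algorithms against a composite reference diagnosis
    (sensitivity, specificity, predictive values, likelihood ratios with
    Wilson score intervals, Cohen's kappa, percent agreement, McNemar's
    test), a kappa-based sample-size calculator for agreement studies, and
    a calibrated synthetic-cohort generator so that every pipeline stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
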