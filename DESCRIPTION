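Package: strokecog
Title: Modeling and Predicting Early Post-Stroke Cognitive Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modeling the early-phase recovery of cognitive
    function after stroke from serial Mini-Mental State Examination
    (MMSE) assessments. Provides exact two-point tailoring of
    logarithmic and linear recovery curves to an individual patient,
    bounded prediction of later scores, group-level time-course
    analysis (Friedman test, exact Wilcoxon signed-rank test, curve
    fits with coefficients of determination), a predicted-versus-actual
    validation pipeline with a within-threshold correctness rule and
    chi-squared model comparison, Fisher-z sample-size calculation for
    correlation designs, and a calibrated synthetic-cohort simulator
    for bounded integer score instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
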