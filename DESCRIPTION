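Package: sidmodels
Title: Signs of Impending Death: Onset Statistics and OR-Rule Prediction Models
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing bedside signs of impending death in
    longitudinal dying-phase cohorts: cohort containers with CSV input and
    output, shock-index derivation from vital signs, per-sign prevalence and
    mortality statistics with backward Kaplan-Meier onset estimation, an
    exhaustive best-subset search over OR-rules of binary predictor events at
    7-day, 72-hour and 24-hour horizons with 10-fold cross-validation, and a
    calibrated synthetic cohort generator for testing the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
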