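Package: dyadphys
Title: Autonomic Physiology Features and Rating Prediction in Dyadic Tracking Tasks
Version: 0.1.0
Authors@R:
    person("dyadphys", "maintainers", email = "maintainers@dyadphys.org",
           role = c("aut", "cre"))
Description: Tools for analysing autonomic physiology (heart rate variability,
    respiration, electrodermal activity) recorded from dyads performing a
    collaborative visuomotor tracking task. Provides a seeded synthetic cohort
    generator, extraction of 23 standard autonomic parameters (time-domain,
    Burg-spectral and Poincare HRV indices; breathing-rate and respiratory
    band-power features; integrated tonic and phasic electrodermal measures),
    objective tracking-error summaries, rating preprocessing, a from-scratch
    quadratic discriminant classifier with leave-one-sample-out and
    leave-one-subject-out cross-validation, macro-F1 scoring, backward feature
    selection, sample-substitution permutation importance, label-permutation
    significance tests, and the accompanying correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
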