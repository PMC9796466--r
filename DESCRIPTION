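Package: actimood
Title: Rest-Activity Rhythm and Mood-Disorder Phenotyping for Accelerometer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Questionnaire-based phenotyping of probable bipolar disorder and
    probable unipolar mania in population cohorts, nonparametric circadian
    rest-activity metrics (average acceleration, M10, L5, relative amplitude,
    interdaily stability, intradaily variability) and sleep-window detection
    from wrist-accelerometer epoch series, objective-versus-subjective sleep
    discrepancy classification, and pairwise case-control comparison
    statistics (covariate-adjusted logistic and multinomial models, Fisher's
    exact fallback for sparse tables, Benjamini-Hochberg false discovery rate
    control, chi-squared and one-way ANOVA descriptives with effect sizes).
    Includes a synthetic three-group cohort generator with configurable
    demographics, questionnaire response probabilities and actigraphy signal
    parameters, so the full pipeline can be exercised and validated without
    access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
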