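Package: gazeclass
Title: Area-of-Interest Gaze Fixation Metrics and Count-Over-Cutoff
    Discrimination for Autism Screening Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for short eye-tracking stimulus batteries in
    which gaze dwell inside named rectangular areas of interest (AoIs) is
    summarised as percentage fixation time and used to separate autism
    spectrum disorder (ASD) from typical development (TD). Provides the
    eight-stimulus battery definition with configurable AoI geometry, a
    seeded synthetic-cohort generator whose 50 Hz gaze streams reproduce
    published group fixation moments, availability-based participant
    exclusion, independent t tests with per-stimulus Bonferroni levels and
    Cohen's d effect-size screening, within-group correlations against
    social-responsiveness and IQ scores, rank-based ROC analysis with
    Youden-optimal directional cutoffs, and the multi-item count-over-cutoff
    classifier reported as sensitivity, specificity, and likelihood ratios
    across count thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    car,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
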