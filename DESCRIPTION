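Package: rxpatterns
Title: Treatment-Pattern, Matching and Cost Analysis for Longitudinal
    Prescription Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for retrospective pharmacoepidemiologic cohort studies
    built on longitudinal electronic-medical-record-like prescription data.
    Implements gap-based classification of medication persistence,
    discontinuation (with summer drug-holiday handling), switching,
    restarting and augmentation over a fixed follow-up window; index-date
    cohort construction with configurable inclusion and exclusion rules;
    1:1 greedy nearest-neighbour propensity-score matching with a caliper
    and calibration/balance diagnostics; healthcare resource utilization
    counting with configurable unit-cost attribution and consumer-price
    inflation adjustment; and the accompanying inferential toolkit
    (Pearson chi-squared, rank-sum, t, log-rank, negative-binomial and
    gamma generalized linear models). A seeded synthetic record generator
    and a deterministic worked-example fixture support testing and
    method evaluation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
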