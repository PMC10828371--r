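Package: sweetspot
Title: Discovery of Optimal Physiological Phenotype Values in Aging Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting "sweet spots" - optimal values of continuous
    physiological phenotypes - from cross-sectional aging-cohort data. The
    package builds five unit-interval health-deficit instruments (a deficit
    accumulation frailty index, major-disease and chronic-condition counts,
    and rank-normalized cognitive and physical composites), screens phenotypes
    for variance heterogeneity between the healthiest and least-healthy strata
    with the Brown-Forsythe test under Bonferroni control, estimates
    sex-specific breakpoints by one-breakpoint segmented regression with a
    pseudo-score test for the change in slope, and plans replication via a
    score-statistic power analysis. A synthetic-cohort generator with planted
    ground truth makes the whole pipeline testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
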