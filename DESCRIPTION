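Package: DIIprofiler
Title: Dietary Inflammatory Index Scoring and Inflammatory Proteome Profiling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the Dietary Inflammatory Index (DII) from seven-day
    dietary records and a food-composition table, splits a cohort at the
    median DII, tests Olink-style NPX protein abundances for differential
    expression between the resulting groups, trains a gradient-boosted
    classifier of DII group membership with ROC evaluation, and performs
    hypergeometric over-representation analysis of the differential proteins.
    Includes a seeded synthetic-cohort generator with planted effects so the
    whole pipeline is testable end to end without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    xgboost,
    jsonlite,
    yaml,
    fgsea,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
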