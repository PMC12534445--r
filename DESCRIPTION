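Package: explorindex
Title: Exploration Index Analysis for Immature Primate Object Use
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies individual variation in object use and exploratory
    behavior from coded ethological bout records. Computes a composite
    Exploration Index (the sum of five z-transformed per-individual object-use
    metrics), partitions individuals into high and low explorers by exact
    one-dimensional k-means with elbow selection of k, and fits the study's
    inferential models from scratch: ordinary least squares, robust regression
    by Huber's M-estimator, bout-level logistic regression of atypical use on
    age, the Mann-Whitney U test with an exact enumeration null, and a one-way
    random-intercept variance-components model (REML and ANOVA estimators) for
    the intraclass correlation across maternal siblings. Includes a validated
    CSV data model, a deterministic in-study fixture, a synthetic-data
    generator with the assumed statistical structure, and an end-to-end
    pipeline that renders structured JSON or markdown reports.
License: MIT
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
    MASS,
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
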