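Package: strokeClock
Title: Hyperacute Blood Transcriptome Time-Course Analysis and a
    Transcriptional Stroke Clock
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing hyperacute blood gene-expression time
    courses after experimental ischemic stroke. Implements per-gene linear
    models over a time-factor design with empirical-Bayes variance
    moderation and a moderated F-statistic across neighboring-timepoint
    contrasts, K-means clustering of rank-standardized temporal profiles
    under a Spearman correlation distance, rule-based classification of
    cluster centroids into named temporal archetypes, cross-ranking of
    literature candidate biomarker panels, and a nearest-profile "stroke
    clock" estimator of hours since stroke onset with leave-one-animal-out
    evaluation. A synthetic-data generator reproduces the study design
    (8 animals, six sampling times over 24 h, one missing sample) with
    ground-truth archetype labels so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0)
biocViews: GeneExpression, TimeCourse, DifferentialExpression,
    Clustering, Microarray
Config/testthat/edition: 3
RoxygenNote: 7.3.3
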