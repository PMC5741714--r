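Package: trajmark
Title: Trajectory Clustering of Developmental Transcriptomes with
    Single-Cell Marker Integration
Version: 0.9.0
Authors@R:
    person("trajmark", "developers", email = "trajmark@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for bulk developmental RNA-seq time courses
    integrated with cell-type signatures derived from labeled single-cell
    RNA-seq. Provides a negative-binomial Wald differential-expression core,
    trajectory-based estimation of the number of temporal expression
    clusters (percentile discretization of signed Z-score profiles followed
    by trajectory counting and k-means), marker discovery by pairwise
    differential-expression voting across cell subtypes, hypergeometric
    gene-set and marker-set enrichment, and prediction of cell-type-specific
    differentiation drivers as developmentally repressed exclusive markers.
    Includes negative-binomial simulators for both data modalities with
    planted ground truth so that the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
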