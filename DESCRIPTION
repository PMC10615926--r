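Package: surgal
Title: Active Learning Annotation Efficiency for Surgical Video Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prospective comparison of uncertainty-driven active learning
    against equidistant sampling for annotating multi-feature tags on
    surgical-video frames. Provides a feature taxonomy (ordinal blood and
    smoke scales, binary anatomy and instrument presence), a seeded
    synthetic procedure-video generator with ground-truth feature tracks
    and simulated noisy raters, Bayesian image classifiers with
    Monte-Carlo dropout, majority-vote consensus annotation, evaluation
    statistics (one-vs-rest F1 with hierarchical macro aggregation,
    Edwards-corrected McNemar tests, Fleiss kappa with rater merging), a
    multi-cycle annotation-protocol orchestrator, and an automatically
    generated per-procedure report with videogram, feature barcodes and
    duration summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
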