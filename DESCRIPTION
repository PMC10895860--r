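Package: markerbench
Title: Marker Gene Selection Methods and Benchmarking for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A self-contained toolkit for selecting cluster-specific marker
    genes in single-cell RNA-seq count data and for benchmarking the
    statistical selectors that popular analysis frameworks expose. Implements
    the two-group statistics used for marker selection (Wilcoxon rank-sum with
    optional tie correction, Welch and Student t-tests, an exact detection
    test, gene-wise logistic regression, a two-group Poisson GLM, ROC power,
    Cohen's d, detection-proportion log fold-changes, cosine scores) together
    with one-vs-rest and pairwise comparison strategies, p-value aggregation,
    multiple-testing correction and the ranking conventions that differ
    between analysis frameworks. Includes a gamma-Poisson count simulator with
    cluster-specific multiplicative differential-expression factors and a
    ground-truth marker score, an evaluation harness (recovery, predictive
    performance, concordance, stability, selected-gene characteristics,
    p-value census), and diagnostics that expose documented pathologies such
    as p-value underflow and log fold-change formula divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite,
    e1071,
    FNN,
    fitdistrplus,
    limma,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
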