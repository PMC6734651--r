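Package: BoolScreen
Title: Boolean-Implication Biomarker Screening and Prognostic Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Step-function (StepMiner-style) binarization of log2 expression
    matrices, genome-wide asymmetric Boolean-implication search ("X-low
    implies Y-high") with sparse-quadrant statistics and permutation false
    discovery rates, candidate filtering by population support and
    differential expression, two-gene patient subgrouping, and the
    accompanying clinical statistics battery: baseline-table tests
    (chi-square, Fisher, pooled t, tie-corrected Mann-Whitney), Kaplan-Meier
    curves, log-rank tests, multivariate Cox models and 2x2 factorial
    chemotherapy interaction (multiplicative term and RERI). Includes a
    seeded synthetic-cohort generator with planted ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
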