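Package: ifnscore
Title: Interferon Signature Scoring and Cross-Platform Expression Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying interferon-driven transcription across
    heterogeneous gene-expression cohorts. Implements probe-level filtering and
    LOWESS normalization for two-channel arrays, linear-space probe-to-gene
    collapsing, fold-change normalization to internal healthy controls, and a
    cross-platform comparison matrix on shared genes; SAM-style permutation
    differential expression with automatic fudge-factor selection; derivation
    of a consensus interferon-inducible core signature from pooled in vitro
    stimulation experiments and a per-sample IFN score (median linear fold
    change of the top signature genes); per-array hypergeometric gene-set
    module maps; average-linkage hierarchical clustering with the uncentered
    correlation similarity metric; SVD-based missing-value imputation and PCA;
    exact Spearman correlation; delta-delta-Ct conversion for qPCR panels; and
    a synthetic multi-platform cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
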