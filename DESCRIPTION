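Package: clonalsig
Title: Clonal Gene Signature Discovery from Multi-Region Tumor Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers and validates clonal prognostic gene signatures from
    multi-region tumor RNA-seq data. Computes per-gene intratumor and
    intertumor heterogeneity scores, classifies clonally expressed ("Q4")
    genes with high between-tumor but low within-tumor variability, scores
    per-gene clustering concordance across tumor regions, and assembles a
    five-step filter chain (median-expression filter, univariable Cox screen,
    Q4 intersection, concordance cutoff, lasso-penalized Cox selection with
    unpenalized refit) into a linear per-sample risk score. Includes tertile
    risk stratification with Kaplan-Meier / log-rank and multivariable Cox
    evaluation, hypergeometric gene-set overlap statistics, copy-number
    amplification and deletion frequency profiles with rank correlation, and
    a seeded synthetic-data generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
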