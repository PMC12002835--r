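Package: vascage
Title: Age-Correlation Screening and Regulon Attrition Analysis for Arterial Omics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying age-dependent remodelling of the arterial
    transcriptome and proteome. Implements a transcriptome-wide Pearson
    age-correlation screen over multiple arteries with Benjamini-Hochberg
    q-values, pan-arterial and extended concordance filters, an effect-size
    proxy ranking (mean TPM x slope), and age-bin summaries; a gene-panel
    "regulon attrition" statistic testing whether a panel's age-correlation
    coefficients deviate from the genome-wide median (one-sample Wilcoxon
    signed-rank with exact tie-aware p-values); confounder-adjusted linear
    models and 2^-ddCt relative quantification for qPCR; and a label-free
    proteomics differential-expression stage with two-sample t statistics,
    permutation-based false discovery rate control, downshifted-Gaussian
    imputation of intensity-dependent missing values, z-scoring, hierarchical
    clustering, and principal component analysis. A seeded synthetic-data
    module generates ground-truth-labelled expression cohorts and two-group
    proteomes so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
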