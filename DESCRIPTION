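Package: proteopheno
Title: Proteogenomic Discovery Pipeline for pQTL, PWAS and Mendelian
    Randomization Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of a cerebrospinal-fluid
    proteogenomic inference chain: aptamer-level quality control and
    normalization for SomaScan-style proteomic matrices, covariate-adjusted
    linear pQTL scanning, fixed-effect inverse-variance meta-analysis with
    heterogeneity statistics, phenome-wide association (PheWAS) of sentinel
    variants with FDR control, summary-statistic conditional and joint
    stepwise SNP selection with LD pruning, proteome-wide association
    (PWAS) via cis+trans SNP weight models, two-sample Mendelian
    randomization (Wald ratio and inverse-variance weighting) with
    region-exclusion and cis-only sensitivity configurations, differential
    protein-level contrasts, and cell-type specificity enrichment. Includes
    a synthetic-data module that generates LD-blocked genotypes, aptamer
    matrices with planted genetic effects and measurement artifacts, and a
    liability-threshold disease partially mediated by protein levels, with
    a ledger of planted truth for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    vcfR,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
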