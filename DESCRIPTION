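Package: scdeqtl
Title: Expression QTL and Genotype-by-Clinical-Status Interaction Mapping
    for Sickle Cell Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for joint analysis of gene-expression and
    genome-wide genotype data in a pediatric sickle-cell-disease cohort
    with healthy sibling controls. Provides a synthetic-cohort simulator
    with known ground truth; genotype QC (minor-allele frequency, call
    rate, exact Hardy-Weinberg test) and expression normalization
    (log2 quantile normalization, background knee filtering, technical
    replicate averaging); structure analysis (expression and Eigenstrat
    genotype PCA, REML variance components of leading expression PCs,
    hierarchical clustering, Weir-Cockerham Fst); probe-level ANCOVA with
    per-term FDR control and pairwise contrasts; fast genome-wide eSNP
    scans with local/distal classification and two-tier Bonferroni
    thresholds; peak-association selection and eSNP conditioning; and
    SNP-by-clinical-status interaction mapping with LD pruning, pairwise
    relatedness estimation, and relatedness-aware Q-K mixed-model refits.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
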