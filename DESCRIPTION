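Package: mitoscan
Title: Case-Only Discovery of Mitonuclear Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scanning cohorts for associations between
    mitochondrial and nuclear SNP alleles (mitonuclear combinations).
    Provides analytic power calculations for mitochondrial variant
    eligibility, haploid linkage-disequilibrium pruning of mtSNPs,
    per-cohort case-only logistic-regression scans with principal
    component adjustment and Benjamini-Hochberg false discovery rate
    control, combined-cohort tests for disease-status modulation of
    mitonuclear associations and for mtSNP x nSNP effects on disease
    risk, and a Balding-Nichols stratified cohort simulator so every
    stage is testable without access to cohort genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
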