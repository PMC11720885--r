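Package: salivamp
Title: Salivary Proteomics and Metaproteomics Analysis of Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end, reproducible re-implementation of a salivary
    proteomics/metaproteomics case-control workflow: 16S-rRNA-guided
    construction of sample-specific reduced protein databases, peptide and
    protein quantification-matrix preprocessing with left-censored
    (downshifted-normal) and iterative random-forest imputation,
    lowest-common-ancestor taxonomic profiling of bacterial peptides,
    differential-abundance statistics with Benjamini-Hochberg control,
    rank-based 1D/2D annotation enrichment, hierarchical clustering with
    Fisher enrichment, and covariate-adjusted peptide-clinical-trait
    association models with glycemic-status interaction. Ships a synthetic
    cohort generator that emulates the statistical structure of such studies
    (left-censored intensities over 4-5 decades, planted group effects) so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
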