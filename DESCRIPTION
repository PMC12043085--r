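Package: ieilgl
Title: Immunogenomic Triage of Inborn Errors of Immunity in T-LGL Leukemia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level immunogenomic analysis for T cell large granular
    lymphocyte leukemia (T-LGLL) and related clonal cytotoxic T cell
    expansions. Implements germline triage of rare variants in inborn-errors-
    of-immunity (IEI) genes with a binomial observed-versus-expected
    overrepresentation screen and Benjamini-Hochberg correction,
    high-confidence deleterious (hcD) carrier classification under
    dominant/recessive inheritance rules, clinical immune-defect phenotyping
    against laboratory normal ranges, somatic T cell driver landscapes with
    gene-level copy-number aggregation from segments, TCR repertoire
    normalization by fixed-depth downsampling with diversity and CDR3
    specificity analysis, gene-set expression scoring with percentile
    coexpression calls, and a synthetic cohort generator so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
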