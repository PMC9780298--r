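Package: ctdnaChemoScore
Title: Genomic Instability Metrics and Response Scores from ctDNA Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for circulating tumor DNA (ctDNA) targeted panel
    sequencing in the context of neoadjuvant chemotherapy response prediction
    and prognosis. Implements rule-based somatic variant filtering, the
    copy-number instability (CNI) score from GC-corrected bin read counts
    against a baseline cohort, mutant-allele tumor heterogeneity (MATH),
    tumor mutational burden (TMB), PCA-based discrimination of response
    groups with ROC/AUC, a two-component PCA gene-signature score (nCTPS)
    with maximally selected survival cutoffs and stratified Kaplan-Meier
    analysis, and a multi-omics gene screen combining chi-square
    copy-number tests, copy-number dosage-expression association, gene-set
    intersection, and expression-drug-sensitivity correlation. A synthetic
    cohort generator with full ground truth makes every stage testable
    without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    vcfR
Config/testthat/edition: 3
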