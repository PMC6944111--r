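Package: bcrisk
Title: Construction and Evaluation of Methylation, Genetic and Environmental
    Risk Scores for Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds the three families of blood-based breast-cancer risk
    scores used in nested case-control studies: direction-aware quartile
    counting methylation risk scores (MRS) from beta-value matrices, a
    weighted risk-allele genetic risk score (GRS) with SNP quality control,
    two-locus EM linkage-disequilibrium statistics, LD pruning and surrogate
    SNP substitution, and coefficient-table environmental risk scores (ERS)
    with within-group mean imputation. Provides the matching evaluation
    toolkit (control-quartile odds ratios with Wald intervals, OR per SD,
    AUC with DeLong confidence intervals, repeated stratified k-fold
    cross-validation, Hosmer-Lemeshow calibration, per-CpG association
    scans with Benjamini-Hochberg adjustment) and a synthetic nested
    case-control cohort generator with planted effects for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    pROC,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
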