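Package: prsvar
Title: Polygenic Risk Score Variability Under Replicate Genotype Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the run-to-run variability that genotype imputation
    introduces into polygenic risk scores (PRS). Provides a synthetic
    two-population cohort generator with block linkage disequilibrium, a
    Li-Stephens haplotype-copying imputation emulator with deterministic and
    stochastic modes, PRS computation with ancestry-stratified percentile
    ranking and risk tiers, per-individual percentile-range and
    re-classification statistics with confidence intervals, imputation
    accuracy metrics (dosage R-squared, genotype F-score, imputation quality
    score) with minor-allele-frequency binning, and a per-SNP decomposition of
    score variability into imputation consistency (Gini coefficient) and
    percent variance explained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
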