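Package: smrmt
Title: Multi-Tissue Summary Mendelian Randomization from GWAS and eQTL Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates genome-wide association study (GWAS) summary
    statistics with cis-eQTL summary statistics from multiple tissues to
    test whether gene expression levels are associated with a disease
    phenotype, using the summary-data Mendelian randomization (SMR)
    Wald-ratio estimator with a chi-square test on the product of z-scores.
    Provides allele harmonization of summary tables, per-gene instrument
    selection, per-tissue experiments with Bonferroni control, cross-tissue
    aggregation of significant SNP-gene pairs (tissue counts, gene-by-tissue
    overlap, SNP repetition counts), a generic hypergeometric
    over-representation test, and a synthetic summary-statistics generator
    with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
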