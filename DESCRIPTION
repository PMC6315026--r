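Package: crosstraitr
Title: Cross-Trait Genetic Correlation and Pleiotropy Analysis from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("crosstraitr", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying shared genetic aetiology between two complex
    traits from genome-wide association study (GWAS) summary statistics:
    harmonization and quality control of summary-statistics tables, LD-score
    computation and univariate, cross-trait and stratified LD-score regression
    with block-jackknife standard errors, fixed-effects inverse-variance
    meta-analysis with heterogeneity diagnostics, a region-wide Bonferroni scan
    for pleiotropic risk loci over correlated-variant sets, permutation-based
    variant-set enrichment against chromatin-mark peak intervals, and
    summary-data-based Mendelian randomization (SMR) with the HEIDI
    heterogeneity test. Includes a synthetic-data module that generates
    LD-structured reference panels, bivariate case-control summary statistics
    with known heritability and genetic correlation, cis-eQTL loci and peak
    fixtures, so the full pipeline is testable without consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
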