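Package: mpratools
Title: Differential Activity Analysis for Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Linear-model based differential activity analysis for massively
    parallel reporter assay (MPRA) count data. Summarizes barcode-level RNA
    and DNA counts into element-level log2 activity measures (aggregate and
    average estimators), models the dependence of activity variance on
    element copy number to derive observation-level precision weights,
    and fits precision-weighted linear models with empirical-Bayes variance
    moderation, including consensus-correlation handling of paired allelic
    designs.  Also provides a negative-binomial synthetic data generator, a
    null-resampling procedure for empirical type I error estimation, FDR
    estimation utilities, classical t-test and Fisher exact test baselines,
    and a Taylor-series based power calculator for choosing sequencing depth
    and sample size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
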