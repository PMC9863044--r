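Package: mbmr
Title: Two-Sample Mendelian Randomization for Microbiome Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization of
    gut-microbiota taxa against kidney phenotypes from GWAS summary
    statistics: instrument selection (locus-wide p threshold, greedy LD
    clumping, MAF and F-statistic filters, confounder blocklist,
    outcome-association exclusion), allele harmonization with palindromic
    SNP removal, Wald-ratio, inverse-variance-weighted (fixed and
    multiplicative-random effects), MR-Egger, weighted-median and
    weighted-mode estimators, Cochran's Q, Egger-intercept and MR-PRESSO
    pleiotropy diagnostics, leave-one-out stability analysis, rank-specific
    Bonferroni classification, and reverse-direction analysis. Includes a
    synthetic two-sample GWAS generator with known ground truth so every
    stage is testable without access to consortium data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
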