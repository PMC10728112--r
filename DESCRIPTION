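Package: metamr
Title: Two-Sample Mendelian Randomization Screening for Metabolite-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) screening
    pipeline for testing many exposures (for example, hundreds of blood
    metabolites) against a single disease outcome from GWAS summary
    statistics. Implements instrument selection (p-value thresholding,
    greedy LD clumping, confounder exclusion lists, palindromic-variant
    handling, allele harmonization, F-statistic filtering of weak
    instruments), causal-effect estimation (Wald ratio, fixed- and
    multiplicative random-effects inverse-variance weighting, MR-Egger
    regression with intercept, weighted median with parametric bootstrap),
    and the standard sensitivity battery (Cochran's Q, the MR-Egger
    intercept pleiotropy test, MR-PRESSO global/outlier/distortion tests,
    leave-one-out series, and the Steiger directionality test). A
    summary-level GWAS simulator with known ground truth (causal effect,
    pleiotropy regime, outliers, LD blocks, palindromic alleles) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    withr,
    yaml,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
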