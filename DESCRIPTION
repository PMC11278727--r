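Package: micromr
Title: Two-Sample Mendelian Randomization for Microbiome-Disease Causal Screens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization from GWAS
    summary statistics: instrument selection (genome-wide significance filter,
    greedy LD clumping, F-statistic screen), allele harmonization with
    palindrome and minor-allele-frequency exclusions, Wald-ratio and
    inverse-variance-weighted causal estimation on the odds-ratio scale, and
    the Steiger directionality test. Includes a synthetic summary-statistics
    generator with known ground truth (causal effect, pleiotropy, confounding,
    reverse causation, block LD) so every stage is testable offline, aimed at
    screens of many weakly heritable exposures (e.g. gut microbial taxon
    abundances) against one binary disease outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
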