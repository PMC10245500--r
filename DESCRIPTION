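Package: mrpipe
Title: Two-Sample Mendelian Randomization with Mediation and Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: genome-wide-significant instrument selection with LD clumping
    and F-statistics, effect-allele harmonization (strand flips, palindromic
    SNPs), inverse-variance-weighted, MR-Egger, weighted-median and MR-PRESSO
    causal estimators with Cochran's Q, leave-one-out and distortion
    diagnostics, fixed-effect meta-analysis across cohorts with I-squared,
    and two-step MR mediation by the product-of-coefficients method. Includes
    a summary-statistics simulator with known causal truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
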