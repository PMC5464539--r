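Package: mrpipe
Title: Two-Sample Mendelian Randomization with GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: reading and validating association tables, genome-wide
    instrument selection, LD pruning, recalibration of effects to trait
    standard-deviation units, palindromic-SNP proxy replacement, allele
    harmonization, causal-effect estimation (Wald ratio, inverse-variance
    weighted, profile-likelihood, weighted median, MR-Egger with outlier
    detection), between-strata heterogeneity, funnel and forest plot data,
    analytic power for binary outcomes, and a summary-statistics simulator
    with known truth for method calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
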