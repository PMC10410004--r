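Package: mrsummary
Title: Two-Sample Mendelian Randomization on GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("mrsummary", "maintainers", role = c("aut", "cre"),
    email = "maintainers@mrsummary.example")
Description: A complete two-sample Mendelian randomization workflow for GWAS
    summary statistics: instrument selection with R-squared and F-statistic
    grading, allele harmonization with palindromic-SNP resolution, the
    standard estimator battery (inverse-variance weighted with fixed and
    multiplicative random effects, MR-Egger, simple and weighted median,
    simple and weighted mode), sensitivity diagnostics (Cochran's Q, Egger
    intercept, leave-one-out, MR-PRESSO global/outlier/distortion tests),
    multivariable MR, two-step mediation MR with effect decomposition, and a
    synthetic summary-statistics generator with known ground truth so the
    whole pipeline is exercisable without external downloads. Includes a
    command-line pipeline driver for single pairs, exposure-outcome matrices,
    simulation, and mediation analyses.
License: MIT
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
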