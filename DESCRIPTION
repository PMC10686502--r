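Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    GWAS summary statistics: genome-wide-significant instrument selection with
    greedy LD clumping, effect-allele harmonization with palindromic-variant
    handling, univariable causal estimation (Wald ratio, inverse-variance
    weighted, MR-Egger, weighted median), sensitivity diagnostics (Cochran's Q,
    Egger intercept test, and a simulation-based residual-sum-of-squares
    outlier procedure with global, outlier, and distortion tests),
    multivariable MR for direct effects adjusted for correlated exposures, a
    seeded synthetic summary-statistics generator with known causal truth, and
    a config-driven pipeline that runs an exposure-by-outcome analysis grid
    with full audit trails.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
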