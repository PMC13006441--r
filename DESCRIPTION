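Package: serumscape
Title: Cross-System Profiling of Aptamer-Based Serum Proteomics
Version: 0.1.0
Authors@R:
    person("Serumscape", "Developers", email = "serumscape@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for case-control analysis of
    aptamer-based (SomaScan-style) serum proteome profiles: sample outlier
    detection and leverage-point imputation, duplicate-aptamer resolution,
    covariate-adjusted moderated differential abundance with
    Benjamini-Hochberg false discovery control, PERMANOVA and variance
    partitioning, compartment/tissue/secretome footprint statistics
    (Kolmogorov-Smirnov skew and Hodges-Lehmann shifts), semi-partial
    correlation networks with hypergeometric over-representation, and
    cross-platform (immunoassay) concordance validation. Includes a seeded
    synthetic-data generator emulating the statistical structure of such
    studies so every stage is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    vegan
Config/testthat/edition: 3
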