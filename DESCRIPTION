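Package: comodmap
Title: Coordinated Gene-Module Expression Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Module-map analysis of gene expression cohorts: per-sample
    calls of gene-module induction and repression by hypergeometric tests
    on discretized log-ratio expression, group-level module classification
    across clinical categories, Segal-style gene-consistency scoring with
    an exact or Monte-Carlo Bernoulli-sum null, self-organizing-map
    discrimination of samples with cluster-clinical association tests,
    and differential relevance networks between sample groups via
    Fisher's Z-transformation of Pearson correlations. Includes
    two-channel microarray preprocessing (background filtering, LOWESS
    intensity-dependent normalization, dye-swap merging) and synthetic
    data generators with planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    nortest,
    jsonlite,
    optparse
Config/testthat/edition: 3
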