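Package: plastizea
Title: Expression Plasticity and Genetic Assimilation Analysis for Maize and Teosinte
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparing gene-expression
    plasticity between domesticated maize and its wild ancestor teosinte
    across two controlled environments (Early Holocene vs Modern Ambient).
    Implements negative-binomial differential expression with group
    covariates, cross-taxon response-category classification, Monte-Carlo
    resampling overlap statistics with an exact hypergeometric oracle,
    Fisher-exact term enrichment with Benjamini-Yekutieli correction,
    weighted co-expression networks with topological overlap and
    permutation-based module preservation, and expression-variability
    comparisons across gene categories. Ships a synthetic-data generator
    that plants known gene categories for end-to-end recovery testing.
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
    DESeq2
Config/testthat/edition: 3
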