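Package: gscycles
Title: Genomic Selection Across Multiple Breeding Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating genomic selection across successive cycles
    of a line-breeding program. Implements a two-stage analysis of
    multi-environment trial data (per-trial spatial model selection by AIC
    with Piepho-Moehring heritability, then a weighted across-trial mixed
    model), marker quality control with multivariate-normal EM imputation and
    a genomic relationship matrix, RR-BLUP and G-BLUP prediction with
    prediction-error-variance reliabilities, within-cycle, between-cycle and
    across-cycle cross-validation schemes with bias and outlier diagnostics,
    derived-trait prediction from component-trait breeding values, and a
    multi-cycle breeding-program simulator with known true breeding values
    for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    nlme,
    metafor,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
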