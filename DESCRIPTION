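Package: rfet
Title: Ensemble SVM-RFE Gene Selection for Small-Sample Expression Studies
Version: 0.1.0
Authors@R:
    person("RFET", "Developers", email = "rfet@example.org", role = c("aut", "cre"))
Description: Identifies trait-associated genes from normalized expression
    matrices with very few samples. Implements a per-gene two-sample t-test
    prefilter, linear-kernel SVM recursive feature elimination (SVM-RFE)
    ranking with a compiled SMO solver, repeated n-fold subset-leave-out
    resampling that ensembles many rankings, a re-ranking aggregation
    combining occurrence, rank and elimination weight, and a contrastive
    "tuning gene" filter that removes genes shared between two phenotype
    groups. Includes readers for tab-separated expression matrices, GEO
    Series Matrix files and sample metadata tables, a synthetic-data
    generator with planted differentially expressed genes for end-to-end
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
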