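Package: schemup
Title: Circular Mixture-Model Analysis of Schema Updating in Continuous-Report Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous-report (delayed-estimation) location
    memory experiments that probe the formation and updating of spatial schemas.
    Provides circular-error arithmetic and von Mises densities; a synthetic-data
    generator that emulates a two-group (consolidation vs. no-consolidation)
    schema-shift design; maximum-likelihood fitting of five mixture models of
    response error (target + guessing, with optional schema-mean components)
    compared by AIC/BIC; trial-level posterior attribution of responses to
    mixture components; a participant-level permutation test on pooled-fit group
    differences; and schema-strength analyses (correlations, Fisher r-to-z
    comparison of independent correlations, standardized regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
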