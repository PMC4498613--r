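Package: qeimap
Title: Inclusive Composite Interval Mapping of QTL-by-Environment Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Background-controlled one-dimensional genome scans that separate a
    QTL's average additive effect from its environment-interaction effects in
    biparental populations (doubled haploids, backcross and recombinant inbred
    lines) phenotyped in multi-environment trials. Stepwise regression selects
    marker cofactors per environment, phenotypes are adjusted for the selected
    background, and a constrained ECM algorithm fits two-component normal
    mixtures at every scan position to decompose the LOD score into an
    average-effect component and an interaction component. Includes a
    population and phenotype simulator with a closed-form variance oracle, an
    empirical genome-wide LOD-threshold calculator with a permutation-test
    alternative, and a power/false-discovery evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
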