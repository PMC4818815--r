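Package: shapleyFS
Title: Cooperative-Game Feature Selection for High-Dimensional Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multiphase feature selection for high-dimensional, small-sample
    expression matrices (microarray and related assays). Features are first
    reduced by a univariate filter (Fisher ratio or mutual information), then
    weighted by a Shapley value computed from coalition payoffs built on
    qualitative mutual information (Fisher-ratio utility) and conditional
    mutual information, and finally ranked by a victory-score forward search
    that combines the Shapley weight with symmetric-uncertainty relevance and
    redundancy. Includes a k-fold classification harness, a subset-stability
    (JC) index under resampling, and a seeded synthetic microarray generator
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
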