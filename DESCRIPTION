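Package: gwrep
Title: Replication Rates in Two-Stage GWAS Under Winner's Curse and
    Study-Specific Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models discovery/replication pairs of genome-wide association
    studies at the z-score level with a bivariate normal variance-component
    framework. Jointly accounts for Winner's Curse (selection of significant
    variants on noisy estimates) and study-specific confounding by maximum
    likelihood, including a truncated likelihood for the common case where
    only discovery-significant variants are reported. Provides shrinkage of
    discovery statistics to predicted replication statistics with confidence
    intervals, expected replication rates under Winner's-Curse-only and
    Winner's-Curse-plus-confounding models, a decomposition of discovery
    signal into genetic and confounding variance, a fast simulator of the
    data-generating model, and a command-line interface for fitting,
    prediction and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
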