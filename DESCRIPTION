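Package: sensorscape
Title: Sensor-Domain Profiling and Ecosystem Classification for Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning domain-annotated metagenomes into a taxonomy of
    bacterial environmental sensors. Histidine kinases are located by the
    co-occurrence of their two conserved Pfam domains, their sensory domains
    are excised and clustered into putative sensor families by greedy
    identity/coverage clustering, and the resulting metagenome-by-cluster
    fractional abundance matrix feeds ecosystem richness statistics,
    gradient-boosted ecosystem and condition classifiers, physical-parameter
    regressors, and additive per-feature attributions. A synthetic-corpus
    generator with planted ecosystem structure makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    Rtsne,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
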