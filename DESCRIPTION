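Package: dynetflex
Title: Dynamic Brain Network Reconfiguration via Multilayer Modularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying time-varying community structure in
    functional brain networks. Builds sliding-window dynamic functional
    connectivity from region-by-time signal matrices, optimizes the
    multilayer modularity quality function with an iterated Louvain
    algorithm over the supra-modularity matrix, and derives nodal,
    network-level and global reconfiguration metrics (flexibility,
    promiscuity, cohesion, disjointedness) together with temporal
    core-periphery classification. Group differences are assessed with
    covariate-adjusted permutation tests and Benjamini-Hochberg false
    discovery rate control. A synthetic-cohort generator with planted,
    time-varying community structure provides ground truth for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
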