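Package: stabnet
Title: Stability-Selected Elastic-Net Inference of Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed regulator-to-target gene networks from a
    normalized expression matrix by stability selection over elastic-net
    regressions: samples are repeatedly partitioned into disjoint subgroups,
    a cross-validated elastic-net is fitted per (subgroup, target gene), and
    each candidate edge is scored by the frequency with which its regulator
    is selected across all trials. Edges above a high frequency cutoff form
    the inferred network. Includes precision/recall and rank-based ROC-AUC
    evaluation against DREAM5-style gold-standard edge lists, a sparse
    linear network simulator for benchmarking, and a command-line
    interface with reproducible seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    Rcpp,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
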