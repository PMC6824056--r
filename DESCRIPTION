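Package: wmgraph
Title: Weighted Meta-Graph Prediction of Microbe-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks candidate microbes for human diseases on a heterogeneous
    information network built from an integrated disease similarity network
    (MeSH-style DAG semantic similarity blended with a Gaussian
    interaction-profile kernel), an integrated microbe similarity network
    (gene-family cross-boundary functional similarity blended with a Gaussian
    interaction-profile kernel), and the known disease-microbe bipartite
    network. Pair scores accumulate the contributions of six weighted
    meta-graph patterns through a fixed-point matrix iteration; a literal
    per-pattern enumerator serves as a brute-force oracle. Includes a full
    evaluation harness (global leave-one-out and repeated k-fold
    cross-validation, ROC/AUC, precision/recall/F1 at top-k, recovery curves,
    robustness masking, and a new-disease protocol) and a planted-block
    synthetic data generator so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
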