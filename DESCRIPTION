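Package: rwrneg
Title: Negative Sample Selection for Drug Side-Effect Prediction via
    Random Walk with Restart
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects high-confidence negative drug/side-effect pairs by
    propagating each side effect's known drugs over a weighted
    chemical-chemical interaction network with a random walk with restart,
    and keeping the pairs whose stationary probability falls below a
    threshold. Includes the five-channel maximum-similarity feature
    construction for drug/side-effect pairs, a direct-link (FIRE-style)
    comparator strategy, a cross-validated evaluation harness with ROC and
    precision-recall analysis, and a synthetic-world generator with planted
    community structure and ground-truth negative labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    ranger,
    e1071,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    optparse
Config/testthat/edition: 3
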