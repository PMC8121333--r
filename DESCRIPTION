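Package: pepngrn
Title: Probabilistic Extended Petri Net Inference of Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed, directed gene regulatory networks from discretized
    time-series expression data using the PEPN-GRN family of methods. Adjacent
    time-point transitions of each target gene are classified into four
    evidence types (production, decay, sustained production, sustained decay);
    logical rules over regulator pre-states turn each occurrence into signed
    edge evidence, and per-edge evidence probabilities are aggregated into
    edge scores by unweighted averaging (v1), count weighting (v2), or
    supervised logistic-regression weighting with SMOTE class balancing and
    cross-validation (v3). Includes equal-width, equal-frequency and k-means
    discretizers, AUROC/AUPR and average-rank evaluation against a gold
    standard, the DREAM overall-score formula, a synthetic regulatory-network
    simulator for end-to-end testing, readers and writers for DREAM-style
    expression and edge-list files, and a Petri-net structure export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
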