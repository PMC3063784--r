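Package: metasig
Title: Protein-Imbalance Biomarker Signatures by Exact
    (alpha,beta)-k-Feature-Set Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery of plasma-protein biomarker signatures that encode
    cell-signalling imbalance. A z-scored protein panel is expanded with all
    pairwise-difference "metafeatures", pre-filtered by Fayyad-Irani minimum
    description length (MDL) entropy discretization, and a fixed-size
    signature is selected by exactly solving the (alpha,beta)-k-Feature-Set
    problem with optional forced features, using a deterministic
    branch-and-bound solver. Signatures are evaluated with a 25-member
    multi-family classifier panel, and training samples whose clinical label
    is contradicted by more than a threshold fraction of the panel are
    iteratively pruned. A synthetic-data generator with planted single
    markers, planted imbalance pairs and controlled mislabelling makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    e1071,
    MASS,
    nnet,
    class,
    rpart,
    tree,
    randomForest,
    ranger,
    xgboost,
    glmnet,
    kernlab
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
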