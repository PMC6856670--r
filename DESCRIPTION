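Package: dualpairnet
Title: Drug-Disease Association Prediction with a Dual-Branch Convolutional
    Network over Heterogeneous Pair Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts drug-disease associations from heterogeneous
    pair-embedding matrices built out of four intra-drug similarity views
    (chemical substructure, target-protein domain, target-protein annotation,
    and drug-related disease correlation), an intra-disease similarity matrix,
    and known associations. A dual-branch convolutional neural network scores
    each (drug, disease) pair from its original and nearest-neighbour
    embeddings. Includes the full evaluation protocol: balanced undersampling,
    five-fold cross-validation with leakage-safe per-fold similarity
    recomputation, per-drug ROC and precision-recall AUC, and top-k recall,
    plus a synthetic benchmark generator with planted drug/disease cluster
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
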