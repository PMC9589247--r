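Package: dbpkit
Title: DNA-Binding Protein Prediction from Sequence Features with a 1-D
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting DNA-binding proteins (DBPs) from amino-acid
    sequence. Implements gapped mono-di composition (monoDiKGap), k-mer
    composition and cross-covariance descriptors of position-specific scoring
    matrices (CC-PSSM); two-stage feature selection combining AdaBoost stump
    importance with an ensemble of relevance scores (ANOVA F, mutual
    information, lasso path, mRMR) fused by PageRank and trimmed by forward
    addition; and a native 1-D convolutional neural network classifier with
    six gradient optimizers. Includes a synthetic two-class sequence generator
    with plantable compositional signal and matching synthetic PSSMs so the
    full pipeline is testable without external databases, plus the standard
    binary-classification evaluation suite (ACC, SN, SP, MCC, ROC/AUC,
    precision-recall).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
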