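Package: ctgfusion
Title: Cardiotocography Classification with Apriori Feature Selection and
    Multi-Model Suspect Reassignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying cardiotocography (CTG) feature tables with
    the three-class NSP label (normal / suspect / pathologic). Features are
    screened by a Kruskal-Wallis rank test and a plug-in mutual-information
    filter, then selected by mining per-class frequent itemsets with a
    level-wise Apriori algorithm over equal-frequency-binned attributes and
    fusing the per-class attribute columns. A five-classifier benchmark
    (k-nearest neighbours, Gaussian naive Bayes, logistic regression under
    stochastic gradient descent, AdaBoost, and AdaBoost over random forests)
    evaluates pairwise class combinations, and a four-model voting ensemble
    reassigns suspect records to normal or pathologic, fusing the problem
    from three classes to two. Includes a synthetic CTG generator with
    latent ground truth for suspect records, confusion-matrix metrics, ROC
    and AUC utilities, tidy() and glance() methods, ggplot2 plots, and a
    reproducible end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
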