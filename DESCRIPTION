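Package: kmerselect
Title: Alignment-Free Protein Superfamily Classification with n-Gram
    Features and Statistical Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein sequences as frequency vectors over the fixed
    universe of amino-acid n-grams of length 1 to 3 (8420 descriptors),
    ranks descriptors by a per-class-pair separation statistic whose
    minimum over all pairs scores how well a feature discriminates every
    superfamily simultaneously, and evaluates classifiers trained on the
    selected subset with repeated stratified train/test splits.  Includes
    a synthetic sequence generator with planted class-specific n-grams, a
    multiclass evaluation-metric panel (accuracy, TPR, FPR, sensitivity,
    specificity, precision, recall, F-measure, MCC), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
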