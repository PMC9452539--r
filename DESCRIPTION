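Package: enhancerRF
Title: Enhancer Prediction from DNA Sequences via Statistical Moments and
    Two-Layer Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies DNA enhancer regions and grades their strength from
    200 bp sequence windows. Each sequence is summarised by a 102-dimensional
    super feature vector built from raw, central and discrete orthogonal Hahn
    moments of the row-major sequence matrix, position-relative incidence
    matrices computed in forward and reverse orientation, nucleotide
    composition counts, and accumulative absolute-position vectors. A
    two-layer random-forest cascade separates enhancers from non-enhancers
    and strong from weak enhancers, with out-of-bag error tracking,
    successive-halving tree-count tuning, k-fold/jackknife cross-validation,
    and ROC/PR evaluation. A seeded sequence simulator with tunable
    compositional class separation makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
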