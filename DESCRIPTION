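Package: sdfuse
Title: Stochastic Decision Fusion for Multi-View Ripeness Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-level fusion of per-view multi-label classifier scores
    for ordinal fruit ripeness staging. Implements equal-weight fusion and
    stochastic decision fusion (SDF), in which per-view weight vectors are
    built from the argmax-selected columns of column-normalized confusion
    matrices and applied element-wise before summation and L2 normalization.
    Also provides detector post-processing (IoU, greedy non-maximum
    suppression, the three-part detection loss evaluated on toy tensors),
    one-vs-rest precision/recall/F1 with macro averaging, precision-recall
    curves with area, seeded k-fold splitting, and a Dirichlet-based
    multi-view score simulator with ordinal adjacent-stage confusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
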