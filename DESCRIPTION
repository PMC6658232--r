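Package: crfbridge
Title: Transfer Learning for Clinical Sequence Labeling with Linear-Chain
    Conditional Random Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for slot-filling style information extraction from clinical
    free text. Implements a linear-chain conditional random field (CRF)
    sequence tagger trained with AdaGrad and early stopping; a three-step
    transfer-learning procedure that initializes a target-domain CRF from a
    frozen source-domain CRF through a learned label-correlation bridge, with
    the dominant not-applicable class zeroed at initialization; and skip-gram
    word embeddings with negative sampling, including incremental adaptation
    to a new domain via sentence-averaged initialization of new word vectors
    and split learning rates for new versus previously trained words.
    Ships per-class, macro- and micro-averaged precision/recall/F1 evaluation,
    a paired Wilcoxon signed-rank comparison, random and majority baselines,
    and a synthetic corpus generator so the whole pipeline is testable without
    restricted clinical data.
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
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
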