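Package: rxnrl
Title: Reaction Outcome Prediction Boosted by Reinforcement Learning from
    Negative Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains sequence-to-sequence models for forward chemical
    reaction prediction and improves them with failed (negative) reactions
    through reinforcement learning. Provides SMILES handling and reaction
    dataset input/output, cleaning and splitting utilities, enumeration of
    regiochemical negative products by repositioning a halogen over
    aromatic C-H sites, yield-threshold labeling for high-throughput
    experimentation data, a compact encoder-decoder transformer trained by
    maximum likelihood with beam-search decoding, a reward model built
    from reaction-fingerprint embeddings and an imbalance-aware support
    vector machine, a clipped policy-gradient tuner anchored to a frozen
    reference policy, evaluation metrics (top-k positive accuracy,
    invalid fraction), multi-seed comparison harnesses, and a synthetic
    toy reaction language with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    ChemmineOB,
    ChemmineR,
    cli,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
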