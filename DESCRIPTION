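Package: solvar
Title: Sequence-Based Prediction of Amino Acid Substitution Effects on
    Protein Solubility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Three-class prediction of whether a single amino acid
    substitution decreases, increases, or has no effect on protein
    solubility, from sequence alone. Implements the full pipeline:
    featurization of substitutions from AAindex physicochemical scales,
    substitution-type and residue-group indicator matrices, neighborhood
    window composition, and protein length; gradient-boosted decision-tree
    classifiers in both a single three-class and a two-layer cascade
    (decreasing vs not-decreasing, then increasing vs no-effect)
    architecture; recursive feature elimination; position-grouped
    train/test splitting and cross-validation that never separates
    substitutions at one site; and a class-imbalance-normalized evaluation
    suite (per-class PPV/NPV/sensitivity/specificity, correct prediction
    ratio, generalized squared correlation). A synthetic-fixture generator
    with a planted, feature-visible label rule makes the whole pipeline
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    xgboost
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
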