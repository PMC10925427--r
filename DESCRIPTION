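Package: znsite
Title: Zinc-Binding Site Prediction and Validation in Macromolecular Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts zinc-ion locations and their coordinating ligands in
    protein structures from geometry alone. Candidate sites are enumerated
    from cysteine SG and histidine ring atoms under empirical distance
    restraints, the most probable zinc position is deduced with
    subgroup-specific geometric strategies, and candidates are verified
    either by hydrophobicity-profile correlation (3- and 4-residue sites)
    or by a five-learner majority-vote ensemble (2-residue sites).
    Also provides bond-valence-based validation of modelled metal sites
    (valence, completeness and environment agreement scores),
    intersection-over-union and distance-threshold evaluation metrics, and
    a synthetic coordination-geometry generator used by the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    nnet,
    pROC,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
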