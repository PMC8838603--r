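Package: srpnet
Title: Synthetic Accessibility from Reaction Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a directed substance-level reaction knowledge graph from
    atom-mapped reaction SMILES, designates reactant versus reagent roles by
    inverse-template application and fingerprint matching, computes each
    product's shortest reaction path (SRP) from purchasable building blocks,
    labels compounds as easy- or hard-to-synthesize at an SRP cut-off, curates
    balanced datasets by leader clustering, and trains and evaluates three
    families of synthetic-accessibility classifiers (random forest on
    physicochemical descriptors, a feed-forward network on ECFP4 fingerprints,
    and a communicative message-passing graph network). Ships a synthetic
    reaction-corpus generator with known ground truth so the whole pipeline is
    testable without external reaction databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
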