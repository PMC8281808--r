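Package: pharmakg
Title: Heterogeneous Pharmaceutical Knowledge-Graph Embeddings with Textual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building, embedding and completing typed heterogeneous
    pharmaceutical knowledge graphs. Provides a typed triple data model with
    drug, protein, pathway, category and ATC-code entities, readers and
    writers for triple and text-attribute tables plus a fixture-scale
    DrugBank-like XML parser with ATC hierarchy expansion, four triple
    scoring functions (TransE, DistMult, ComplEx, SimplE), logistic and
    margin ranking losses with type-restricted negative sampling, an
    Adagrad mini-batch trainer, three schemes for injecting entity text
    into embedding learning (initialization, alignment, graph
    augmentation), filtered type-aware link-prediction evaluation with
    per-relation and macro-averaged mean reciprocal rank, and synthetic
    knowledge-graph generators so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    yaml,
    xml2,
    ggplot2,
    generics,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
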