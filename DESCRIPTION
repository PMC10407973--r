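Package: kbrelex
Title: Knowledge-Base-Refined Weak Supervision for Drug-Protein Relation Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building weakly labelled drug-protein relation
    extraction datasets by filtering model predictions against a
    chemical-gene knowledge base, and for training relation classifiers in
    two phases (weak pretraining followed by fine-tuning on human labels).
    Includes readers and writers for DrugProt-style corpus files and
    CTD-style interaction tables, sentence splitting and entity-marker
    preprocessing, a desk-scale hashed n-gram reference classifier with a
    linear warmup/decay learning-rate schedule, DrugProt micro-F1
    evaluation with per-type reports and confusion matrices, prediction
    ensembling, a seeded synthetic corpus generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
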