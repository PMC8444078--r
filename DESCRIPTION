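Package: medkgqa
Title: Medical Knowledge-Graph Question Answering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a signed, weighted disease-symptom-drug knowledge graph
    from structured medical instruction records using dictionary-anchored
    semantic-template rules, classifies question intent with an
    information-gain model over concept-generalized one-hot features, and
    answers questions either by a seed-clamped weighted path-ranking
    inference on the graph (disease diagnosis, drug recommendation) or by
    direct property lookup, rendering final answers from slot templates.
    Includes a synthetic corpus generator with known ground truth,
    evaluation metrics (per-category accuracy, disease coverage), and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
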