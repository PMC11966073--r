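Package: suppkb
Title: Dietary Supplement Knowledge Graph Construction and Graph-Grounded Question Answering
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a typed property graph of dietary supplement knowledge from
    multi-source record extracts: ingestion and cleaning of product, ingredient
    and assertion records, concept normalization against a controlled
    vocabulary with tiered candidate prioritization, greedy cross-source entity
    integration with deterministic identifier assignment, and triple
    construction with deduplication. On top of the graph it provides an
    embedding-based entity linker (cosine similarity with an inclusive 0.75
    threshold), a retrieval-augmented question-answering pipeline with fixed
    relation routing and a deterministic template generator, a true-or-false
    and multiple-choice question generator, and a bootstrap accuracy
    evaluation harness. A synthetic multi-source fixture generator with full
    ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
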