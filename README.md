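# suppkb

Construction and querying of a dietary-supplement knowledge base as a typed
property graph, with a graph-grounded retrieval-augmented question-answering
(RAG) pipeline and a bootstrap evaluation harness — all runnable offline and
reproducibly from seeds.

## The problem

Consumers and clinicians ask questions like *"Which disease is Omega-3
effective for?"* or *"Does Ginkgo interact with Warfarin?"*. Free-standing
language models answer such questions fluently but unreliably; curated
supplement databases answer them reliably but only through structured
queries. `suppkb` implements the pipeline that connects the two worlds:

1. **Ingestion & cleaning** — product, ingredient and assertion records from
   multiple source databases (delimited text dialects) are parsed row by row,
   nonsense ingredient names (shorter than two characters, or consisting
   solely of digits/punctuation, such as `"8"` or `"%."`) are filtered,
   recorded field variants (e.g. `"U.S.A."` vs `"United States of America"`)
   are unified through an alias table, and within-source synonym rows are
   collapsed by their shared group id.
2. **Concept normalization** — entity names are matched against a controlled
   vocabulary (CUI, term, semantic types, preferred flag), restricted by
   semantic type per category, and resolved by a three-tier prioritization:
   exact match marked preferred, then any exact match, then the preferred
   candidate with the highest similarity; otherwise the entity stays
   unmapped.
3. **Greedy integration** — per entity type, a seed source initializes the
   vocabulary and later sources fold in: records merge when they share a CUI
   or an identical normalized name (products: identical product name and
   company name). Every concept receives a deterministic type-prefixed
   identifier (`DI0000001`, `DP0000001`, ...), and assertions become
   deduplicated `<head, relation, tail>` triples with provenance and rating
   attributes.
4. **Typed graph** — 7 concept types (ingredient, product, disease, drug,
   sign/symptom, therapeutic class, system organ class) and 6 relation
   types; each supported (head type, tail type) pair routes to exactly one
   relation (`DSI–DISEASE → is_effective_for`, `DSI–DRUG → interacts_with`,
   `DSP–DSI → has_ingredient`, ...), so relations never need to be inferred.
   Graphs export to bulk-importer CSV tables and to openCypher `MERGE`
   statements.
5. **Entity linking & RAG** — every concept name is embedded into a unit
   vector (the default provider is a deterministic character-trigram hashing
   embedder; a commercial embedding API can be plugged in through the same
   contract). A question mention links to the concept with the highest
   cosine similarity, accepted iff it is **at least 0.75** (inclusive). The
   pipeline extracts mentions, links them, routes the relation from the
   concept-type pair, runs the graph query, and renders an answer grounded
   only in the retrieved triples; when nothing links, it flags the answer as
   outside the knowledge base and delegates to the generator (fallback).
6. **Evaluation** — true-or-false and five-option multiple-choice questions
   are generated from the graph's effectiveness and interaction triples
   (negatives from sampled non-edges; one option is always "None of the
   above"), and systems are scored by bootstrap: 100 questions per
   repetition, 10 repetitions — 1000 answers per question type — with
   optional source holdout at the retrieval stage.

A synthetic fixture generator (`synthesize()`) emulates cross-source
overlap, synonymy, address variants and nonsense-name noise with full ground
truth, so the entire pipeline is testable without any licensed source data.

## Worked example

```r
library(suppkb)

g <- kg_new()
add <- function(ty, n, name, syn = character(0))
  kg_add_concept(g, new_concept(make_idisk_id(ty, n), ty, name,
                                synonyms = syn, sources = "MSKCC"))
add("DSI", 1, "Vitamin C", syn = "Ascorbic acid")
add("DSI", 2, "Omega-3 Fatty Acids")
diseases <- c("Common cold", "Cardiovascular disease", "Lupus", "Cancer",
              "Depression", "High cholesterol", "Atherosclerosis")
for (k in seq_along(diseases)) add("DISEASE", k, diseases[k])
kg_add_triple(g, "DI0000001", "is_effective_for", "DD0000001")
for (k in 2:7)
  kg_add_triple(g, "DI0000002", "is_effective_for", make_idisk_id("DISEASE", k))

idx <- build_entity_index(g)
rag_answer("Which disease is Omega-3 Fatty Acids effective for?", g, idx)$answer
#> "Omega-3 Fatty Acids are effective for: - Cardiovascular disease - Lupus
#>  - Cancer - Depression - High cholesterol - Atherosclerosis"

answer_tf("Is it true that Vitamin C is effective for the common cold?",
          g, idx)$answer
#> "True"

answer_mcq("Out of the given list, which disease is Vitamin C effective for?",
           c("Bladder stones", "Common cold", "Stroke",
             "Bleeding hemorrhoids", "None of the above"), g, idx)$answer
#> "Common cold"
```

Every entity named in a template answer corresponds to a retrieved triple —
the renderer cannot hallucinate by construction. Holding out the source that
contributed a triple (`exclude_sources = "MSKCC"`) removes its evidence at
retrieval, and the true-or-false answer above flips to `"False"`.

The same pipeline is scriptable from a shell:

```sh
inst/cli/suppkb synth    --out fixtures --seed 7
inst/cli/suppkb build-kg --config fixtures/config.yaml --out kg
inst/cli/suppkb ask      --kg kg "Which disease is <name> effective for?"
```

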