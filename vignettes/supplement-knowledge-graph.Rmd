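---
title: "Building and querying a dietary-supplement knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and querying a dietary-supplement knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(suppkb)
```

## The model

`suppkb` represents dietary-supplement knowledge as a typed property graph.
Concepts come in seven closed types — dietary supplement ingredient (DSI),
dietary supplement product (DSP), disease, drug, sign/symptom, therapeutic
class (TC) and system organ class (SOC) — and relations in six closed types.
The central structural assumption, inherited from the supplement domain, is
that the relation between two concepts is fully determined by their types:

```{r}
relation_routing()
```

Only these six ordered pairs carry a relation; asking for any other pair
(say disease–drug) is an error, not an empty result. Because the assignment
is a bijection, the question-answering layer never embeds or predicts
relations — it routes them from the types of the linked entities. Two of the
six names are fixed by the domain's usage (effectiveness for ingredient–
disease, interaction for ingredient–drug) and `has_ingredient` can only
link a product to its ingredients; the remaining three names attach to the
remaining pairs by elimination on their objects: an *adverse reaction* is a
sign/symptom, an *adverse effect on* takes an organ class, and a
*therapeutic class* is exactly the TC type. This is the package's reading of
an assignment the source material leaves implicit, and it is centralized in
`relation_routing()` so a different reading is a one-row change.

Triples `<head, relation, tail>` are a set: re-inserting an existing triple
merges provenance (source labels) and fills missing rating attributes
rather than duplicating, and the collapse is recorded in a merge log.
Effectiveness ratings annotate ingredient–disease triples and interaction
ratings ingredient–drug triples; product attributes (company name and
address, purpose, risk) and ingredient attributes (background, safety,
mechanism of action, source material) live on concepts.

## Cleaning and normalization

Ingredient-name cleaning drops a name exactly when, after trimming, it has
fewer than two characters or consists solely of digits, punctuation/symbol
characters and whitespace — the rule that removes noise entries like `"8"`
or `"%."`. The character classes are Unicode (`\p{N}`, `\p{P}`, `\p{S}`), a
well-defined superset of ASCII punctuation that covers the percent sign;
further patterns are configuration (`extra_patterns`), not hard-coded rules.

Vocabulary mapping restricts candidates by semantic type per category and
resolves them in three tiers: (1) similarity exactly 1 and marked preferred;
(2) similarity exactly 1; (3) marked preferred with the highest similarity;
otherwise the entity stays unmapped. Two deliberate choices:

* **Tie-breaking.** Within a tier, ties resolve to the lexicographically
  smallest CUI. The source procedure is silent on ties; any fixed rule
  works, and this one makes resolution a pure function of the candidate
  *set* (order-invariance is property-tested against a literal brute-force
  scan).
* **The matcher is pluggable.** The similarity measure of the original
  concept-matching tool is not specified, so `vocab_candidates()` accepts
  any scorer returning values in [0, 1]. The default is normalized
  Levenshtein similarity (`1 - d/max(nchar)`), which is deterministic,
  dependency-free and easy to verify by hand (one edit over 11 characters
  gives `r round(string_similarity("comon cold", "common cold"), 4)`).
  When mapping unmapped names in a build (`map_cuis`), a candidate floor
  (`min_similarity`, default 0.85) prevents tier 3 from assigning a CUI to
  an arbitrary junk string, standing in for the retrieval threshold the
  original matching tool applies internally.

## Greedy integration

For each entity type the configured seed source initializes the entity
vocabulary; later sources fold in one record at a time. A record merges into
an existing concept iff its merge key matches — same CUI or identical term
name for DSI/disease/drug/symptom (and TC/SOC), identical (product name,
company name) for products — and founds a new concept otherwise. "Identical
term name" is evaluated case-insensitively after whitespace collapse:
source casing is noisy, and byte equality would under-merge; the
normalization is centralized in `norm_name()` and every merge decision is
auditable in the returned ledger (reason codes `same-CUI`,
`identical-name`, `product-name+company`, `new-entity`).

Identifiers are type-prefixed, zero-padded and assigned in processing order
(seed-source order, then record order), so a rebuild from identical inputs
reproduces identical identifiers — this is the package's determinism
guarantee, tested end to end. The order in which non-seed sources fold in is
configuration; the merge rules make final *counts* order-independent in the
tested settings, but the ledger records whichever order ran. Attribute
conflicts keep the first-seen (seed-priority) value and log the collision;
manual quality review is thereby replaced by an exported audit artifact
(ledger plus conflict log), not an interactive step.

## Entity linking and question answering

Every concept name — preferred names and, by default, synonyms — is embedded
as a unit vector. The default provider hashes character trigrams of the
normalized name onto 64 signed coordinates and L2-normalizes; it is
deterministic bit-for-bit, needs no network, and its fingerprint is recorded
in the index so mixed-provider indexes are rejected. A real embedding API
drops in through the same `embedding_provider()` contract. Synonyms vote for
their concept by maximum similarity.

A mention links to the argmax-similarity concept iff the cosine similarity
is **at least 0.75** — the comparison is inclusive, taking the stated
acceptance rule literally, and the boundary is tested on constructed vector
pairs whose cosine is exactly representable (0.75 = 3/4 with components
whose squares are exact binary fractions). Ties break to the smaller
concept id; raising the threshold can only turn matches into no-matches
(monotonicity, property-tested).

Question answering composes: mention extraction (default: longest-match
dictionary scan over graph names; the contract accepts an LLM extractor),
linking, intent detection (a small keyword lexicon deciding which type the
question asks about — deterministic where the original system delegates
this to a prompt), relation routing, an openCypher rendering of the planned
query plus its backend-neutral structured form, retrieval from the
in-memory store, and a template generator that renders answers *only* from
retrieved triples — grounding holds by construction. If no mention links,
the answer is flagged as not available in the knowledge base and the
generator answers alone (`fallback_used`). Retrieval honours a source
holdout set at triple level: a triple is visible only if some source
outside the holdout attests it.

## Question generation and bootstrap scoring

True-or-false items phrase existing triples ("Is it true that X is
effective for Y?", gold True) and uniformly sampled same-type non-edges
(gold False), 1:1 by default — the simplest null consistent with both
answers occurring, since the source protocol shows only a positive example.
Multiple-choice items carry the gold entity, three same-type distractors
not linked to the subject, and "None of the above" — five options, matching
the published example; a configurable fraction (default 0.2) omits the true
answer so "None of the above" is sometimes correct, keeping that option
informative. Bootstrap evaluation draws 100 questions per repetition, 10
repetitions (1000 answers per question type); draws are with replacement by
default — the protocol's wording is loose, and both modes are supported.

## What the synthetic generator emulates — and what it does not

`synthesize()` produces four sources: `srcA` (products + ingredients with
purpose/risk/address), `srcB` (products + ingredients with within-source
synonym rows sharing a group id), `srcC` (ingredients + assertions with
rating text) and `srcD` (assertions duplicating a fraction of `srcC`,
exercising cross-source triple deduplication — the dialect standing in for a
source whose content derives from already-integrated knowledge). It injects
cross-source overlap, synonym variants, country-spelling variants in
addresses, and nonsense ingredient rows, and records full ground truth.

Default rates are chosen once as plausible for curated supplement sources:
20% of entities carry synonyms, 30% appear in a second source, 80% of
mappable entities have a vocabulary CUI, 5% of ingredient rows are noise,
30% of product rows spell their country as a variant. Default sizes
(150 ingredients, 180 products, 70 diseases, 60 drugs, 40 symptoms, 15
therapeutic classes, 8 organ classes — 523 entities, ~300 assertions) keep
a full build and a 2×1000-question evaluation comfortably inside a test
run while leaving every code path (merging by CUI, by name, by product key;
grouping; dedup) exercised many times over.

One structural rule makes ground truth recoverable *exactly* under the
stated merge rules: the first source record of an entity always uses its
canonical name, and entities without a CUI appear under their canonical
name in every source (synonym-named cross-source records are emitted only
for CUI-covered entities). Real data offers no such guarantee — real
sources contain unlinkable aliases, typos and genuinely ambiguous names, so
a passing recovery test demonstrates that the *rules are implemented
faithfully*, not that the rules resolve every real-world entity. Likewise
the pronounceable-token names make string similarity behave nontrivially
but are far more separable than real supplement nomenclature, and the
generator does not imitate real label text or real source magnitudes.

## Numerical and degenerate-input choices

* Cosine similarity is undefined for zero vectors and raises an error
  rather than returning 0; empty mentions are input errors.
* The trigram embedder pads with boundary markers so any non-empty
  normalized name yields a nonzero vector.
* Name-index collisions (two concepts of one type sharing a name) keep the
  first-registered concept — relevant only for adversarial inputs, since
  integration merges such records instead.
* Malformed source rows are rejected per row with a logged reason and never
  abort a build; `parsed + rejected = n` is an invariant.
* Per-type totals are plain arithmetic sums and are invariant under
  concept/triple reordering.

## Known limitations

* The dictionary extractor cannot find mentions that are not graph names;
  recall on free-form questions therefore depends on the synonym inventory
  (or on plugging in a model-based extractor).
* Intent detection is keyword-based English; questions avoiding the lexicon
  fall back to an unfiltered neighborhood query.
* The linker scans exhaustively — adequate at this scale, quadratic memory
  would not be; an approximate-nearest-neighbor engine is deliberately out
  of scope.
* The published full-scale entity counts and the accuracies of commercial
  language models are not reproducible here: they depend on licensed source
  data and external APIs. The package reproduces the published *arithmetic*
  (count-table and protocol totals) and the *behavioural* properties
  (boundary, prioritization, recovery, closed-loop accuracy) instead.
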