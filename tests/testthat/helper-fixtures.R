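# Fixture builders shared across the suite. All fixtures are built in code.

# Small knowledge base holding the worked examples: Vitamin C / common cold,
# Omega-3 Fatty Acids with its six diseases, a drug interaction, and MCQ
# distractor diseases. The Vitamin C effectiveness triple is sourced from
# "MSKCC" so holdout behaviour can be exercised.
demo_kg <- function() {
  g <- kg_new()
  add <- function(ty, n, name, syn = character(0), src = "MSKCC")
    kg_add_concept(g, new_concept(make_idisk_id(ty, n), ty, name,
                                  synonyms = syn, sources = src))
  add("DSI", 1, "Vitamin C", syn = "Ascorbic acid")
  add("DSI", 2, "Omega-3 Fatty Acids")
  add("DSI", 3, "Ginkgo")
  add("DISEASE", 1, "Common cold")
  add("DISEASE", 2, "Cardiovascular disease")
  add("DISEASE", 3, "Lupus")
  add("DISEASE", 4, "Cancer")
  add("DISEASE", 5, "Depression")
  add("DISEASE", 6, "High cholesterol")
  add("DISEASE", 7, "Atherosclerosis")
  add("DISEASE", 8, "Bladder stones")
  add("DISEASE", 9, "Stroke")
  add("DISEASE", 10, "Bleeding hemorrhoids")
  add("DRUG", 1, "Warfarin")
  add("DRUG", 2, "Aspirin")
  add("SYMPTOM", 1, "Nausea")
  kg_add_triple(g, "DI0000001", "is_effective_for", "DD0000001",
                sources = "MSKCC")
  for (k in 2:7)
    kg_add_triple(g, "DI0000002", "is_effective_for", make_idisk_id("DISEASE", k),
                  sources = "NMCD")
  kg_add_triple(g, "DI0000003", "interacts_with", "DG0000001",
                sources = "MSKCC")
  kg_add_triple(g, "DI0000001", "interacts_with", "DG0000002",
                sources = "NMCD")
  kg_add_triple(g, "DI0000003", "has_adverse_reaction", "SY0000001",
                sources = "MSKCC")
  g
}

# Random letter-only name (safe for pipe-joined fields).
rand_name <- function(len = sample(4:10, 1)) {
  paste0(sample(LETTERS, 1), paste(sample(letters, len, replace = TRUE),
                                   collapse = ""))
}

# Randomized graph with valid typed triples, for round-trip property tests.
random_kg <- function(seed) {
  set.seed(seed)
  g <- kg_new()
  ids <- list()
  for (ty in concept_types()) {
    n <- sample(1:4, 1)
    ids[[ty]] <- vapply(seq_len(n), function(k) {
      attrs <- character(0)
      if (ty == "DSP" && runif(1) < 0.5)
        attrs <- c(company_name = rand_name(), product_purpose = rand_name())
      if (ty == "DSI" && runif(1) < 0.5)
        attrs <- c(background = rand_name())
      kg_add_concept(g, new_concept(
        make_idisk_id(ty, k), ty, rand_name(),
        synonyms = if (runif(1) < 0.4) c(rand_name(), rand_name())
          else character(0),
        cui = if (runif(1) < 0.5) sprintf("C%07d", sample(999, 1))
          else NA_character_,
        attributes = attrs,
        sources = sample(c("srcA", "srcB", "srcC"), sample(1:2, 1))))
      make_idisk_id(ty, k)
    }, character(1))
  }
  rt <- relation_routing()
  for (i in seq_len(nrow(rt))) {
    for (h in ids[[rt$head_type[i]]]) {
      for (t in ids[[rt$tail_type[i]]]) {
        if (runif(1) < 0.4) {
          attrs <- character(0)
          if (rt$relation[i] == "is_effective_for" && runif(1) < 0.5)
            attrs <- c(effectiveness_rating = "Effective")
          if (rt$relation[i] == "interacts_with" && runif(1) < 0.5)
            attrs <- c(interaction_rating = "Major")
          kg_add_triple(g, h, rt$relation[i], t, attributes = attrs,
                        sources = sample(c("srcA", "srcB"), 1))
        }
      }
    }
  }
  g
}

# Literal three-tier brute-force resolver, kept independent of resolve_cui():
# scans the rows repeatedly, tier by tier, tracking the lexicographically
# smallest qualifying CUI by explicit comparison.
oracle_resolve <- function(cand) {
  if (is.null(cand) || nrow(cand) == 0) return(NA_character_)
  pick <- NA_character_
  for (i in seq_len(nrow(cand)))
    if (cand$similarity[i] == 1 && cand$preferred[i])
      if (is.na(pick) || cand$cui[i] < pick) pick <- cand$cui[i]
  if (!is.na(pick)) return(pick)
  for (i in seq_len(nrow(cand)))
    if (cand$similarity[i] == 1)
      if (is.na(pick) || cand$cui[i] < pick) pick <- cand$cui[i]
  if (!is.na(pick)) return(pick)
  best_sim <- -1
  for (i in seq_len(nrow(cand)))
    if (cand$preferred[i] && cand$similarity[i] > best_sim)
      best_sim <- cand$similarity[i]
  if (best_sim >= 0) {
    for (i in seq_len(nrow(cand)))
      if (cand$preferred[i] && cand$similarity[i] == best_sim)
        if (is.na(pick) || cand$cui[i] < pick) pick <- cand$cui[i]
    return(pick)
  }
  NA_character_
}

# Random candidate sets for the resolver equivalence property.
random_candidates <- function() {
  n <- sample(0:6, 1)
  if (n == 0)
    return(data.frame(cui = character(0), similarity = numeric(0),
                      preferred = logical(0), stringsAsFactors = FALSE))
  data.frame(
    cui = sprintf("C%03d", sample(1:12, n, replace = TRUE)),
    similarity = ifelse(runif(n) < 0.35, 1, round(runif(n), 3)),
    preferred = runif(n) < 0.5,
    stringsAsFactors = FALSE)
}

# A unit vector pair with exactly the requested cosine (components chosen so
# that all squares are exact in binary floating point when cosine = 0.75).
boundary_vectors <- function(first = 0.75) {
  u <- c(1, rep(0, 7))
  v <- c(first, rep(0.25, 7))
  list(u = u, v = v)
}
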