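#' @title Controlled-vocabulary concept mapping
#' @description
#' Maps source entity names to controlled-vocabulary concept identifiers
#' (CUIs). Candidate generation restricts vocabulary entries by semantic type
#' per entity category and scores them with a pluggable string-similarity
#' matcher; the tiered resolution strategy then picks a CUI or leaves the
#' entity unmapped.
#' @name concept-mapping
NULL

#' Default semantic-type allow-lists per entity category
#'
#' Editable configuration: each category maps to the semantic-type codes its
#' vocabulary candidates may carry. Defaults cover standard disorder,
#' chemical/substance, and sign-symptom groupings.
#'
#' @return Named list of character vectors keyed by concept type.
#' @export
default_semantic_types <- function() {
  list(
    DSI = c("T109", "T121", "T127", "T168", "T002", "T197"),
    DISEASE = c("T047", "T048", "T019", "T046", "T191"),
    DRUG = c("T121", "T109", "T195", "T200"),
    SYMPTOM = c("T184")
  )
}

#' Read a controlled-vocabulary file
#'
#' Delimited table with columns `cui`, `term`, `semantic_types` (pipe-joined
#' codes), `preferred` (0/1 or true/false). The (cui, term) pairs must be
#' unique.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return A data.frame with columns `cui`, `term`, `semantic_types`
#'   (list-column of character vectors), `preferred` (logical).
#' @export
read_vocabulary <- function(path, delim = "\t") {
  df <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "",
                          na.strings = character(0))
  need <- c("cui", "term", "semantic_types", "preferred")
  if (!all(need %in% names(df)))
    stop_suppkb("vocabulary file '%s' lacks column(s): %s", path,
                paste(setdiff(need, names(df)), collapse = ", "),
                class = "suppkb_parse_error")
  if (anyDuplicated(paste(df$cui, df$term, sep = "\t")))
    stop_suppkb("vocabulary file '%s' has duplicate (cui, term) pairs", path,
                class = "suppkb_parse_error")
  data.frame(
    cui = df$cui, term = df$term,
    semantic_types = I(lapply(df$semantic_types, split_pipe)),
    preferred = tolower(df$preferred) %in% c("1", "true", "t", "yes"),
    stringsAsFactors = FALSE)
}

#' Default string-similarity matcher
#'
#' Normalized Levenshtein similarity: `1 - d(a, b) / max(nchar(a), nchar(b))`
#' on normalized names, clamped to [0, 1]. Exact (normalized) matches score 1.
#' Any alternative scorer returning values in [0, 1] can be plugged into
#' [vocab_candidates()].
#'
#' @param a,b Character scalars.
#' @return Similarity in [0, 1].
#' @export
string_similarity <- function(a, b) {
  a <- norm_name(a); b <- norm_name(b)
  if (!nzchar(a) || !nzchar(b)) return(0)
  d <- as.numeric(utils::adist(a, b))
  max(0, min(1, 1 - d / max(nchar(a), nchar(b))))
}

#' Generate vocabulary match candidates for an entity name
#'
#' Restricts the vocabulary to entries whose semantic types intersect the
#' category's allow-list, then scores every surviving term against the query
#' name. Results carry the matched CUI, term, similarity and preferred flag.
#'
#' @param name Entity name to map.
#' @param category Entity category: one of `"DSI"`, `"DISEASE"`, `"DRUG"`,
#'   `"SYMPTOM"`.
#' @param vocab Vocabulary data.frame from [read_vocabulary()].
#' @param semantic_types Allow-list configuration (see
#'   [default_semantic_types()]).
#' @param scorer Function `(name, term) -> similarity in [0, 1]`.
#' @param min_similarity Drop candidates scoring below this (default 0, keep
#'   all).
#' @return Data.frame with columns `cui`, `term`, `similarity`, `preferred`,
#'   sorted by decreasing similarity then cui.
#' @export
vocab_candidates <- function(name, category, vocab,
                             semantic_types = default_semantic_types(),
                             scorer = string_similarity,
                             min_similarity = 0) {
  category <- match.arg(category, c("DSI", "DISEASE", "DRUG", "SYMPTOM"))
  empty <- data.frame(cui = character(0), term = character(0),
                      similarity = numeric(0), preferred = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(vocab) == 0) return(empty)
  allowed <- semantic_types[[category]]
  keep <- vapply(vocab$semantic_types, function(st)
    length(intersect(st, allowed)) > 0, logical(1))
  vocab <- vocab[keep, , drop = FALSE]
  if (nrow(vocab) == 0) return(empty)
  sim <- vapply(vocab$term, function(tm) scorer(name, tm), numeric(1))
  if (any(sim < 0 | sim > 1))
    stop_suppkb("scorer returned similarity outside [0, 1]",
                class = "suppkb_bad_scorer")
  out <- data.frame(cui = vocab$cui, term = vocab$term, similarity = sim,
                    preferred = vocab$preferred, stringsAsFactors = FALSE)
  out <- out[out$similarity >= min_similarity, , drop = FALSE]
  out <- out[order(-out$similarity, out$cui, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve match candidates to a single CUI
#'
#' Tiered prioritization over the candidate set:
#' tier 1 — similarity exactly 1 and marked preferred; tier 2 — similarity
#' exactly 1 regardless of the preferred flag; tier 3 — marked preferred, at
#' the highest similarity among preferred candidates. When no tier applies,
#' no CUI is assigned (`NA`). Ties within a tier break by lexicographically
#' smallest CUI, so the result does not depend on candidate order.
#'
#' @param candidates Data.frame with columns `cui`, `similarity`, `preferred`
#'   (extra columns ignored), e.g. from [vocab_candidates()].
#' @return A single CUI string, or `NA_character_` when unmapped.
#' @export
resolve_cui <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NA_character_)
  stopifnot(all(c("cui", "similarity", "preferred") %in% names(candidates)))
  tier1 <- candidates$similarity == 1 & candidates$preferred
  if (any(tier1)) return(min(candidates$cui[tier1]))
  tier2 <- candidates$similarity == 1
  if (any(tier2)) return(min(candidates$cui[tier2]))
  pref <- candidates[candidates$preferred, , drop = FALSE]
  if (nrow(pref) > 0) {
    best <- pref$similarity == max(pref$similarity)
    return(min(pref$cui[best]))
  }
  NA_character_
}

#' Map a batch of names to CUIs
#'
#' Convenience wrapper: candidates then resolution per name.
#'
#' @inheritParams vocab_candidates
#' @param names Character vector of entity names.
#' @return Named character vector of CUIs (`NA` where unmapped), named by the
#'   input names.
#' @export
map_names_to_cuis <- function(names, category, vocab,
                              semantic_types = default_semantic_types(),
                              scorer = string_similarity) {
  out <- vapply(names, function(nm)
    resolve_cui(vocab_candidates(nm, category, vocab,
                                 semantic_types = semantic_types,
                                 scorer = scorer)),
    character(1))
  names(out) <- names
  out
}
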