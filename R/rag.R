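#' @title Graph-grounded question answering
#' @description
#' End-to-end question answering over the knowledge graph: mention
#' extraction, entity linking, relation routing by concept-type pair
#' (relations themselves are deliberately not embedded), graph query
#' planning, triple retrieval, and answer composition. Extraction and
#' generation are pluggable contracts; the defaults are deterministic (a
#' longest-match dictionary extractor over graph names and a template
#' renderer grounded only in retrieved triples), so the pipeline runs offline
#' and reproducibly. When no mention links to the graph, the pipeline flags
#' the answer as outside the knowledge base and delegates to the generator
#' (the fallback path).
#' @name rag
NULL

relation_phrase <- function(relation) {
  c(is_effective_for = "are effective for",
    has_therapeutic_class = "have therapeutic class",
    has_adverse_effect_on = "have adverse effects on",
    has_adverse_reaction = "have adverse reactions including",
    has_ingredient = "contain",
    interacts_with = "interacts with")[[relation]]
}

#' Longest-match dictionary mention extractor
#'
#' Returns an extractor closure that scans a question for the graph's entity
#' names (preferred names and synonyms), case-insensitively, preferring
#' longer names, and keeps non-overlapping matches left to right.
#'
#' @param g A `kg` object.
#' @return Function `question -> data.frame(mention, start, end)`.
#' @export
dictionary_extractor <- function(g) {
  names_all <- unique(unlist(lapply(g$concepts, function(cp)
    c(cp$preferred_name, cp$synonyms)), use.names = FALSE)) %||% character(0)
  names_all <- names_all[order(-nchar(names_all), names_all)]
  function(question) {
    q_low <- tolower(question)
    taken <- rep(FALSE, nchar(question))
    hits <- list()
    for (nm in names_all) {
      st <- gregexpr(tolower(nm), q_low, fixed = TRUE)[[1]]
      if (st[1] == -1) next
      for (s in st) {
        e <- s + nchar(nm) - 1L
        if (any(taken[s:e])) next
        taken[s:e] <- TRUE
        hits[[length(hits) + 1L]] <- data.frame(
          mention = substr(question, s, e), start = s, end = e,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, hits) %||%
      data.frame(mention = character(0), start = integer(0),
                 end = integer(0), stringsAsFactors = FALSE)
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

#' Keyword-based question intent: which concept type is asked about
#'
#' A small lexicon decides the target type of the answer (drug for
#' interaction questions, disease for effectiveness questions, and so on).
#' Returns `NA` when no keyword matches.
#'
#' @param question Question text.
#' @return A concept type code or `NA_character_`.
#' @export
detect_intent <- function(question) {
  q <- tolower(question)
  if (grepl("therapeutic class", q)) return("TC")
  if (grepl("organ", q)) return("SOC")
  if (grepl("interact|\\bdrug", q)) return("DRUG")
  if (grepl("side effect|adverse|symptom", q)) return("SYMPTOM")
  if (grepl("ingredient|contain", q)) return("DSI")
  if (grepl("disease|effective|treat", q)) return("DISEASE")
  NA_character_
}

cypher_label <- function(type) type

#' Plan a graph query from linked concepts
#'
#' One linked concept yields a neighborhood plan under the relation routed
#' from (concept type, asked-about type); two linked concepts whose types
#' form a supported pair yield an edge-existence plan. The plan carries both
#' an openCypher rendering and a backend-neutral structured form.
#'
#' @param g A `kg` object.
#' @param linked_ids Character vector of linked concept ids (>= 1).
#' @param intent_type Concept type the question asks about (see
#'   [detect_intent()]); may be `NA` for an unfiltered neighborhood.
#' @return A list of class `query_plan`: `kind` ("neighborhood"/"edge"),
#'   `head_id`, `tail_id` (edge only), `relation` (may be `NA`), `reversed`,
#'   `cypher`.
#' @export
plan_query <- function(g, linked_ids, intent_type = NA_character_) {
  linked_ids <- linked_ids[!is.na(linked_ids)]
  if (length(linked_ids) == 0)
    stop_suppkb("no linked concepts; the question must fall back",
                class = "suppkb_fallback")
  types <- vapply(linked_ids, function(id) kg_concept(g, id)$concept_type,
                  character(1))
  if (length(linked_ids) >= 2) {
    a <- linked_ids[[1]]; b <- linked_ids[[2]]
    routed <- route_relation(types[[1]], types[[2]])
    head_id <- if (routed$reversed) b else a
    tail_id <- if (routed$reversed) a else b
    ht <- kg_concept(g, head_id)$concept_type
    tt <- kg_concept(g, tail_id)$concept_type
    cy <- sprintf(
      "MATCH (h:%s {idisk_id: '%s'})-[r:%s]->(t:%s {idisk_id: '%s'}) RETURN h, r, t",
      cypher_label(ht), head_id, routed$relation, cypher_label(tt), tail_id)
    return(structure(list(kind = "edge", head_id = head_id, tail_id = tail_id,
                          relation = routed$relation,
                          reversed = routed$reversed, cypher = cy),
                     class = "query_plan"))
  }
  id <- linked_ids[[1]]
  ty <- types[[1]]
  relation <- NA_character_
  reversed <- FALSE
  if (!is.na(intent_type) && intent_type != ty) {
    routed <- route_relation(ty, intent_type)
    relation <- routed$relation
    reversed <- routed$reversed
  }
  cy <- if (is.na(relation))
    sprintf("MATCH (h:%s {idisk_id: '%s'})-[r]-(t) RETURN h, r, t",
            cypher_label(ty), id)
  else if (!reversed)
    sprintf("MATCH (h:%s {idisk_id: '%s'})-[r:%s]->(t:%s) RETURN h, r, t",
            cypher_label(ty), id, relation, cypher_label(intent_type))
  else
    sprintf("MATCH (h:%s)-[r:%s]->(t:%s {idisk_id: '%s'}) RETURN h, r, t",
            cypher_label(intent_type), relation, cypher_label(ty), id)
  structure(list(kind = "neighborhood", head_id = id, tail_id = NA_character_,
                 relation = relation, reversed = reversed, cypher = cy),
            class = "query_plan")
}

#' Execute a query plan against the in-memory graph
#'
#' @param g A `kg` object.
#' @param plan A `query_plan`.
#' @param exclude_sources Source labels to hold out at triple level.
#' @return Data.frame of retrieved triples (see [kg_neighbors()]).
#' @export
retrieve_triples <- function(g, plan, exclude_sources = character(0)) {
  if (plan$kind == "edge") {
    nb <- kg_neighbors(g, plan$head_id, relation = plan$relation,
                       exclude_sources = exclude_sources)
    nb <- nb[nb$head_id == plan$head_id & nb$tail_id == plan$tail_id, ,
             drop = FALSE]
    rownames(nb) <- NULL
    return(nb)
  }
  rel <- if (is.na(plan$relation)) NULL else plan$relation
  kg_neighbors(g, plan$head_id, relation = rel,
               exclude_sources = exclude_sources)
}

#' Deterministic template answer generator
#'
#' Renders an answer grounded exclusively in the retrieved triples: a
#' neighborhood plan lists the neighbor entities under the relation phrase; an
#' edge plan renders a yes/no sentence. With no plan (fallback), the renderer
#' only states that the knowledge is not available in the knowledge base. A
#' generative model can replace this via the same `(question, plan, triples,
#' g)` contract.
#'
#' @param question Question text.
#' @param plan A `query_plan`, or `NULL` on the fallback path.
#' @param triples Retrieved triples data.frame (possibly empty).
#' @param g A `kg` object.
#' @return Answer text.
#' @export
template_generator <- function(question, plan, triples, g) {
  if (is.null(plan))
    return(paste("The specific knowledge is not available within the",
                 "knowledge base; no grounded answer can be given."))
  if (plan$kind == "edge") {
    head_nm <- kg_concept(g, plan$head_id)$preferred_name
    tail_nm <- kg_concept(g, plan$tail_id)$preferred_name
    phrase <- relation_phrase(plan$relation)
    if (nrow(triples) > 0)
      return(sprintf("Yes: %s %s %s.", head_nm, phrase, tail_nm))
    return(sprintf("No: there is no recorded %s relationship between %s and %s.",
                   plan$relation, head_nm, tail_nm))
  }
  head_nm <- kg_concept(g, plan$head_id)$preferred_name
  if (nrow(triples) == 0)
    return(sprintf("No %s facts are recorded for %s.",
                   if (is.na(plan$relation)) "related" else plan$relation,
                   head_nm))
  nbs <- vapply(triples$neighbor_id, function(id)
    kg_concept(g, id)$preferred_name, character(1))
  rel <- plan$relation
  if (is.na(rel))
    return(sprintf("%s is related to: %s", head_nm,
                   paste(sprintf("- %s", nbs), collapse = " ")))
  sprintf("%s %s: %s", head_nm, relation_phrase(rel),
          paste(sprintf("- %s", nbs), collapse = " "))
}

link_mentions <- function(mentions, index, threshold) {
  if (nrow(mentions) == 0)
    return(data.frame(mention = character(0), idisk_id = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE))
  res <- lapply(mentions$mention, function(m)
    link_mention(m, index, threshold = threshold))
  data.frame(mention = mentions$mention,
             idisk_id = vapply(res, `[[`, character(1), "idisk_id"),
             similarity = vapply(res, `[[`, numeric(1), "similarity"),
             stringsAsFactors = FALSE)
}

#' Answer a free-text question over the graph
#'
#' Full pipeline: extract mentions, link them, plan and run the graph query,
#' and compose the answer. When no mention links, the generator is invoked
#' without retrieved context and the plan is flagged `fallback_used`.
#'
#' @param question Question text.
#' @param g A `kg` object.
#' @param index An `entity_index` over `g`.
#' @param extractor Mention extractor (default: [dictionary_extractor()]
#'   over `g`).
#' @param generator Answer generator (default: [template_generator()]).
#' @param threshold Linking threshold (default 0.75, inclusive).
#' @param exclude_sources Source labels held out from retrieval.
#' @return List with `answer` (text) and `plan` (list: `mentions`, `linked`,
#'   `query` (a `query_plan` or `NULL`), `triples`, `fallback_used`).
#' @export
rag_answer <- function(question, g, index, extractor = NULL, generator = NULL,
                       threshold = 0.75, exclude_sources = character(0)) {
  extractor <- extractor %||% dictionary_extractor(g)
  generator <- generator %||% template_generator
  mentions <- tryCatch(extractor(question), error = function(e)
    stop_suppkb("mention extraction failed: %s", conditionMessage(e),
                class = "suppkb_stage_extract"))
  linked <- link_mentions(mentions, index, threshold)
  ok <- linked$idisk_id[!is.na(linked$idisk_id)]
  if (length(ok) == 0) {
    ans <- generator(question, NULL, NULL, g)
    return(list(answer = ans,
                plan = list(mentions = mentions, linked = linked,
                            query = NULL, triples = NULL,
                            fallback_used = TRUE)))
  }
  qp <- tryCatch(plan_query(g, unique(ok), detect_intent(question)),
                 error = function(e)
                   stop_suppkb("query planning failed: %s",
                               conditionMessage(e),
                               class = "suppkb_stage_plan"))
  triples <- retrieve_triples(g, qp, exclude_sources = exclude_sources)
  ans <- generator(question, qp, triples, g)
  list(answer = ans,
       plan = list(mentions = mentions, linked = linked, query = qp,
                   triples = triples, fallback_used = FALSE))
}

edge_visible <- function(g, a_id, b_id, exclude_sources = character(0)) {
  ta <- kg_concept(g, a_id)$concept_type
  tb <- kg_concept(g, b_id)$concept_type
  routed <- route_relation(ta, tb)
  head_id <- if (routed$reversed) b_id else a_id
  tail_id <- if (routed$reversed) a_id else b_id
  t <- g$triples[[triple_key(head_id, routed$relation, tail_id)]]
  if (is.null(t)) return(FALSE)
  if (length(exclude_sources) == 0 || length(t$sources) == 0) return(TRUE)
  length(setdiff(t$sources, exclude_sources)) > 0
}

#' Answer a true-or-false question
#'
#' Extracts and links the two entities named in the statement and answers
#' `"True"` exactly when the routed edge between them exists in the graph
#' (holdout sources excluded). When fewer than two entities link, the system
#' abstains (`"ABSTAIN"`), which evaluation scores as incorrect.
#'
#' @inheritParams rag_answer
#' @return List with `answer` in `"True"`/`"False"`/`"ABSTAIN"` and `plan`.
#' @export
answer_tf <- function(question, g, index, extractor = NULL, threshold = 0.75,
                      exclude_sources = character(0)) {
  extractor <- extractor %||% dictionary_extractor(g)
  mentions <- extractor(question)
  linked <- link_mentions(mentions, index, threshold)
  ids <- unique(linked$idisk_id[!is.na(linked$idisk_id)])
  if (length(ids) < 2)
    return(list(answer = "ABSTAIN",
                plan = list(mentions = mentions, linked = linked,
                            fallback_used = TRUE)))
  ok <- tryCatch(edge_visible(g, ids[[1]], ids[[2]], exclude_sources),
                 error = function(e) FALSE)
  list(answer = if (ok) "True" else "False",
       plan = list(mentions = mentions, linked = linked,
                   fallback_used = FALSE))
}

#' Answer a multiple-choice question
#'
#' Links the subject entity from the stem, routes the relation implied by the
#' stem's intent, then checks each option for the corresponding triple. The
#' first option holding the triple is chosen; otherwise `"None of the above"`
#' when offered; otherwise the system abstains.
#'
#' @inheritParams rag_answer
#' @param options Character vector of answer options (>= 2), possibly
#'   including `"None of the above"`.
#' @return List with `answer` (chosen option text or `"ABSTAIN"`) and `plan`.
#' @export
answer_mcq <- function(question, options, g, index, extractor = NULL,
                       threshold = 0.75, exclude_sources = character(0)) {
  stopifnot(length(options) >= 2)
  extractor <- extractor %||% dictionary_extractor(g)
  none_opt <- options[norm_name(options) == "none of the above"]
  real_opts <- options[norm_name(options) != "none of the above"]
  mentions <- extractor(question)
  linked <- link_mentions(mentions, index, threshold)
  ids <- unique(linked$idisk_id[!is.na(linked$idisk_id)])
  if (length(ids) == 0)
    return(list(answer = "ABSTAIN",
                plan = list(mentions = mentions, linked = linked,
                            fallback_used = TRUE)))
  subject <- ids[[1]]
  for (opt in real_opts) {
    hit <- link_mention(opt, index, threshold = threshold)
    if (is.na(hit$idisk_id)) next
    ok <- tryCatch(edge_visible(g, subject, hit$idisk_id, exclude_sources),
                   error = function(e) FALSE)
    if (ok)
      return(list(answer = opt,
                  plan = list(mentions = mentions, linked = linked,
                              subject = subject, fallback_used = FALSE)))
  }
  if (length(none_opt) > 0)
    return(list(answer = none_opt[[1]],
                plan = list(mentions = mentions, linked = linked,
                            subject = subject, fallback_used = FALSE)))
  list(answer = "ABSTAIN",
       plan = list(mentions = mentions, linked = linked, subject = subject,
                   fallback_used = FALSE))
}
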