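#' @title Greedy cross-source entity integration
#' @description
#' Integrates per-type entity records from multiple sources into a knowledge
#' graph. The vocabulary for each type is seeded from the first source in the
#' seed order; every later record merges into an existing concept when its
#' merge key matches, otherwise it founds a new concept. Merge keys: same CUI
#' or identical normalized term name for ingredients, diseases, drugs and
#' symptoms (and TC/SOC); identical (product name, company name) for
#' products. Every concept receives a deterministic type-prefixed identifier
#' in processing order, so rebuilding from the same inputs reproduces the
#' same ids.
#' @name integrate
NULL

# One per-type integration pass; records: list(source, names, cui, attributes,
# record_id). Returns concepts (list) + ledger rows + conflicts.
integrate_type <- function(type, records, seed_source_order) {
  srcs <- vapply(records, `[[`, character(1), "source")
  ord <- order(match(srcs, seed_source_order,
                     nomatch = length(seed_source_order) + 1L),
               seq_along(records))
  concepts <- list()
  cui2idx <- new.env(parent = emptyenv())
  name2idx <- new.env(parent = emptyenv())
  ledger <- vector("list", length(records))
  conflicts <- character(0)
  is_dsp <- type == "DSP"
  for (i in ord) {
    rec <- records[[i]]
    nm <- unique(rec$names)
    cui <- rec$cui %||% NA_character_
    if (is_dsp) {
      keys <- paste(norm_name(rec$product_name), norm_name(rec$company_name),
                    sep = "\t")
      nm <- rec$product_name
    } else {
      keys <- norm_name(nm)
    }
    idx <- NA_integer_
    reason <- "new-entity"
    if (!is_dsp && !is.na(cui) && !is.null(cui2idx[[cui]])) {
      idx <- cui2idx[[cui]]
      reason <- "same-CUI"
    }
    if (is.na(idx)) {
      for (k in keys) {
        if (!is.null(name2idx[[k]])) {
          idx <- name2idx[[k]]
          reason <- if (is_dsp) "product-name+company" else "identical-name"
          break
        }
      }
    }
    if (is.na(idx)) {
      idx <- length(concepts) + 1L
      concepts[[idx]] <- list(
        preferred_name = nm[[1]], names = nm, cui = cui,
        attributes = rec$attributes %||% character(0),
        sources = rec$source)
    } else {
      cp <- concepts[[idx]]
      cp$names <- unique(c(cp$names, nm))
      cp$sources <- unique(c(cp$sources, rec$source))
      if (is.na(cp$cui)) cp$cui <- cui
      else if (!is.na(cui) && cui != cp$cui)
        conflicts <- c(conflicts, sprintf(
          "%s '%s': conflicting cui '%s' vs '%s' (kept first)",
          type, cp$preferred_name, cui, cp$cui))
      newa <- rec$attributes %||% character(0)
      for (k in names(newa)) {
        if (!(k %in% names(cp$attributes)) || is.na(cp$attributes[[k]]))
          cp$attributes[[k]] <- newa[[k]]
        else if (cp$attributes[[k]] != newa[[k]])
          conflicts <- c(conflicts, sprintf(
            "%s '%s': conflicting attribute '%s' (kept first per source priority)",
            type, cp$preferred_name, k))
      }
      concepts[[idx]] <- cp
    }
    if (!is_dsp && !is.na(cui) && is.null(cui2idx[[cui]])) cui2idx[[cui]] <- idx
    for (k in keys) if (is.null(name2idx[[k]])) name2idx[[k]] <- idx
    ledger[[i]] <- data.frame(
      record_id = rec$record_id, concept_type = type, source = rec$source,
      concept_idx = idx, reason = reason, stringsAsFactors = FALSE)
  }
  list(concepts = concepts, ledger = do.call(rbind, ledger) %||%
         data.frame(record_id = character(0), concept_type = character(0),
                    source = character(0), concept_idx = integer(0),
                    reason = character(0), stringsAsFactors = FALSE),
       conflicts = conflicts)
}

#' Integrate entity records into a knowledge graph
#'
#' @param records_by_type Named list keyed by concept type. For every type
#'   except `DSP`, each record is a list with `source`, `names` (character
#'   vector, first entry is the display name), optional `cui`, optional
#'   `attributes` (named character), and `record_id` (stable key for the
#'   merge ledger). `DSP` records instead carry `product_name`,
#'   `company_name`, plus optional `attributes`.
#' @param seed_source_order Character vector listing each source label once;
#'   the first source initializes the per-type entity vocabulary and the rest
#'   are folded in greedily in this order.
#' @return A list with `kg` (the integrated graph), `ledger` (data.frame:
#'   `record_id`, `concept_type`, `source`, `idisk_id`, `reason` with reason
#'   in same-CUI / identical-name / product-name+company / new-entity) and
#'   `conflicts` (character log of attribute/CUI conflicts).
#' @export
integrate_entities <- function(records_by_type, seed_source_order) {
  if (anyDuplicated(seed_source_order))
    stop_suppkb("seed_source_order lists a source more than once",
                class = "suppkb_bad_config")
  g <- kg_new()
  ledgers <- list()
  conflicts <- character(0)
  for (type in intersect(concept_types(), names(records_by_type))) {
    recs <- records_by_type[[type]]
    if (length(recs) == 0) next
    res <- integrate_type(type, recs, seed_source_order)
    ids <- character(length(res$concepts))
    for (j in seq_along(res$concepts)) {
      cp <- res$concepts[[j]]
      ids[[j]] <- make_idisk_id(type, j)
      kg_add_concept(g, new_concept(
        idisk_id = ids[[j]], concept_type = type,
        preferred_name = cp$preferred_name,
        synonyms = setdiff(cp$names, cp$preferred_name),
        cui = cp$cui, attributes = cp$attributes, sources = cp$sources))
    }
    led <- res$ledger
    led$idisk_id <- ids[led$concept_idx]
    led$concept_idx <- NULL
    ledgers[[type]] <- led
    conflicts <- c(conflicts, res$conflicts)
  }
  ledger <- do.call(rbind, ledgers) %||%
    data.frame(record_id = character(0), concept_type = character(0),
               source = character(0), reason = character(0),
               idisk_id = character(0), stringsAsFactors = FALSE)
  rownames(ledger) <- NULL
  list(kg = g, ledger = ledger, conflicts = conflicts)
}

ledger_lookup <- function(ledger) {
  ids <- ledger$idisk_id
  names(ids) <- ledger$record_id
  ids
}

#' Build deduplicated triples from assertions and product compositions
#'
#' Each assertion becomes one triple whose relation follows
#' [route_relation()] of (DSI, object category); each product-ingredient
#' pair becomes a `has_ingredient` triple. Rating text is stored as the
#' effectiveness or interaction rating attribute where the relation carries
#' one. Duplicate triples collapse, merging provenance. Assertions or
#' ingredients naming entities absent from the graph are skipped and logged.
#'
#' @param g Integrated `kg` from [integrate_entities()].
#' @param assertions List of assertion records (see [read_source()]).
#' @param products List of product records; each must carry `record_id`
#'   matching the merge ledger.
#' @param ledger Merge ledger from [integrate_entities()].
#' @return A list with `n_inserted`, `n_merged` (duplicates collapsed), and
#'   `skipped` (data.frame of `kind`, `name`, `reason`).
#' @export
build_triples <- function(g, assertions = list(), products = list(),
                          ledger = NULL) {
  id_of <- if (!is.null(ledger)) ledger_lookup(ledger) else character(0)
  skipped <- list()
  skip <- function(kind, name, reason)
    skipped[[length(skipped) + 1L]] <<- data.frame(
      kind = kind, name = name, reason = reason, stringsAsFactors = FALSE)
  n_inserted <- 0L
  n_merged <- 0L
  for (a in assertions) {
    head_id <- kg_find(g, "DSI", a$subject_name)
    if (is.na(head_id)) { skip("assertion", a$subject_name,
                               "subject not in graph"); next }
    tail_id <- kg_find(g, a$object_category, a$object_name)
    if (is.na(tail_id)) { skip("assertion", a$object_name,
                               "object not in graph"); next }
    rel <- route_relation("DSI", a$object_category)$relation
    attrs <- character(0)
    rt <- a$rating_text %||% NA_character_
    if (!is.na(rt)) {
      if (rel == "is_effective_for") attrs <- c(effectiveness_rating = rt)
      else if (rel == "interacts_with") attrs <- c(interaction_rating = rt)
    }
    new <- kg_add_triple(g, head_id, rel, tail_id, attributes = attrs,
                         sources = a$source)
    if (new) n_inserted <- n_inserted + 1L else n_merged <- n_merged + 1L
  }
  for (p in products) {
    head_id <- unname(id_of[p$record_id] %||% NA_character_)
    if (is.na(head_id)) { skip("product", p$product_name,
                               "product not in ledger"); next }
    for (ing in p$ingredient_names %||% character(0)) {
      tail_id <- kg_find(g, "DSI", ing)
      if (is.na(tail_id)) { skip("product-ingredient", ing,
                                 "ingredient not in graph"); next }
      new <- kg_add_triple(g, head_id, "has_ingredient", tail_id,
                           sources = p$source)
      if (new) n_inserted <- n_inserted + 1L else n_merged <- n_merged + 1L
    }
  }
  list(n_inserted = n_inserted, n_merged = n_merged,
       skipped = do.call(rbind, skipped) %||%
         data.frame(kind = character(0), name = character(0),
                    reason = character(0), stringsAsFactors = FALSE))
}
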