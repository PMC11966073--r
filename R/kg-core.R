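#' @title Typed property-graph core
#' @description
#' The knowledge graph holds concepts of seven fixed types and triples of six
#' fixed relation types. Each (head type, tail type) pair among the six
#' supported pairs routes to exactly one relation, so relation assignment is a
#' deterministic function of the endpoint types and never needs to be learned
#' or embedded.
#' @name kg-core
NULL

#' The seven concept types
#'
#' DSI (dietary supplement ingredient), DSP (dietary supplement product),
#' DISEASE, DRUG, SYMPTOM (sign/symptom), TC (therapeutic class) and SOC
#' (system organ class). The set is closed.
#'
#' @return Character vector of the 7 type codes.
#' @export
concept_types <- function() {
  c("DSI", "DSP", "DISEASE", "DRUG", "SYMPTOM", "TC", "SOC")
}

#' The six relation types
#'
#' @return Character vector of the 6 relation codes.
#' @export
relation_types <- function() {
  c("is_effective_for", "has_therapeutic_class", "has_adverse_effect_on",
    "has_adverse_reaction", "has_ingredient", "interacts_with")
}

#' Allowed concept attribute keys
#'
#' Product concepts carry company/purpose/risk attributes; ingredient concepts
#' carry background/safety/mechanism/source-material attributes.
#'
#' @return Character vector of attribute keys.
#' @export
concept_attribute_keys <- function() {
  c("company_name", "company_address", "product_purpose", "product_risk",
    "background", "safety", "mechanism_of_action", "source_material")
}

#' Allowed triple attribute keys
#'
#' Effectiveness ratings annotate ingredient-disease triples; interaction
#' ratings annotate ingredient-drug triples.
#'
#' @return Character vector of attribute keys.
#' @export
triple_attribute_keys <- function() {
  c("interaction_rating", "effectiveness_rating")
}

#' The relation routing table
#'
#' A bijection between the six supported ordered (head type, tail type) pairs
#' and the six relation types. Products link to their ingredients; ingredients
#' link to diseases (effectiveness), drugs (interactions), signs/symptoms
#' (adverse reactions), therapeutic classes, and system organ classes (adverse
#' effects).
#'
#' @return A data.frame with columns `head_type`, `tail_type`, `relation`.
#' @export
relation_routing <- function() {
  data.frame(
    head_type = c("DSP", "DSI", "DSI", "DSI", "DSI", "DSI"),
    tail_type = c("DSI", "DISEASE", "SYMPTOM", "DRUG", "TC", "SOC"),
    relation  = c("has_ingredient", "is_effective_for", "has_adverse_reaction",
                  "interacts_with", "has_therapeutic_class",
                  "has_adverse_effect_on"),
    stringsAsFactors = FALSE
  )
}

#' Route a concept-type pair to its relation
#'
#' Returns the unique relation defined for the ordered pair, accepting the
#' reversed order as well (user questions name entities in either order); in
#' that case `reversed` is `TRUE` and the caller must swap head and tail
#' before storing or querying a triple.
#'
#' @param head_type,tail_type Concept type codes (see [concept_types()]).
#' @return A list with elements `relation` (relation code) and `reversed`
#'   (logical).
#' @examples
#' route_relation("DSI", "DISEASE")  # is_effective_for, forward
#' route_relation("DRUG", "DSI")     # interacts_with, reversed
#' @export
route_relation <- function(head_type, tail_type) {
  head_type <- match.arg(head_type, concept_types())
  tail_type <- match.arg(tail_type, concept_types())
  rt <- relation_routing()
  i <- which(rt$head_type == head_type & rt$tail_type == tail_type)
  if (length(i) == 1L)
    return(list(relation = rt$relation[i], reversed = FALSE))
  i <- which(rt$head_type == tail_type & rt$tail_type == head_type)
  if (length(i) == 1L)
    return(list(relation = rt$relation[i], reversed = TRUE))
  stop_suppkb("no relation defined for concept-type pair (%s, %s)",
              head_type, tail_type, class = "suppkb_no_relation")
}

#' Create an empty knowledge graph
#'
#' The graph is an environment-backed object with reference semantics:
#' `kg_add_concept()` and `kg_add_triple()` modify it in place. It maintains a
#' (type, normalized name) index covering every preferred name and synonym,
#' and a merge log recording every duplicate-triple collapse.
#'
#' @return An object of class `kg`.
#' @export
kg_new <- function() {
  g <- new.env(parent = emptyenv())
  g$concepts <- list()
  g$triples <- list()
  g$name_index <- new.env(parent = emptyenv())
  g$merge_log <- character(0)
  class(g) <- "kg"
  g
}

#' Construct a concept record
#'
#' @param idisk_id Unique identifier string (see [make_idisk_id()]).
#' @param concept_type One of [concept_types()].
#' @param preferred_name Nonempty display name.
#' @param synonyms Character vector of alternative names.
#' @param cui Optional controlled-vocabulary identifier (`NA` if unmapped).
#' @param attributes Named character vector/list; keys must come from
#'   [concept_attribute_keys()].
#' @param sources Character vector of source-database labels.
#' @return A list of class `kg_concept`.
#' @export
new_concept <- function(idisk_id, concept_type, preferred_name,
                        synonyms = character(0), cui = NA_character_,
                        attributes = character(0), sources = character(0)) {
  concept_type <- match.arg(concept_type, concept_types())
  if (!is.character(preferred_name) || length(preferred_name) != 1L ||
      !nzchar(trimws(preferred_name)))
    stop_suppkb("concept preferred_name must be a nonempty string",
                class = "suppkb_invalid_concept")
  attributes <- unlist(attributes) %||% character(0)
  if (length(attributes) == 0) attributes <- character(0)
  if (length(attributes)) {
    attributes <- vapply(attributes, as.character, character(1))
    bad <- setdiff(names(attributes), concept_attribute_keys())
    if (length(bad))
      stop_suppkb("unknown concept attribute key(s): %s",
                  paste(bad, collapse = ", "),
                  class = "suppkb_invalid_concept")
  }
  structure(list(
    idisk_id = idisk_id,
    concept_type = concept_type,
    preferred_name = preferred_name,
    synonyms = sort(unique(setdiff(as.character(synonyms), preferred_name))),
    cui = if (length(cui) == 1 && !is.na(cui) && nzchar(cui))
      as.character(cui) else NA_character_,
    attributes = attributes,
    sources = sort(unique(as.character(sources)))
  ), class = "kg_concept")
}

#' Deterministic type-prefixed identifier
#'
#' Zero-padded sequential identifiers, e.g. ingredient `DI0000001`, product
#' `DP0000001`.
#'
#' @param concept_type One of [concept_types()].
#' @param n Positive integer sequence number.
#' @return Identifier string.
#' @export
make_idisk_id <- function(concept_type, n) {
  prefix <- c(DSI = "DI", DSP = "DP", DISEASE = "DD", DRUG = "DG",
              SYMPTOM = "SY", TC = "TC", SOC = "SO")[[
                match.arg(concept_type, concept_types())]]
  sprintf("%s%07d", prefix, as.integer(n))
}

#' Add a concept to a graph
#'
#' Registers the concept under its id and indexes its preferred name and all
#' synonyms under (type, normalized name).
#'
#' @param g A `kg` object.
#' @param concept A `kg_concept` (see [new_concept()]).
#' @return The concept id, invisibly.
#' @export
kg_add_concept <- function(g, concept) {
  stopifnot(inherits(g, "kg"), inherits(concept, "kg_concept"))
  id <- concept$idisk_id
  if (!is.null(g$concepts[[id]]))
    stop_suppkb("duplicate idisk_id '%s'", id, class = "suppkb_duplicate_id")
  g$concepts[[id]] <- concept
  for (nm in c(concept$preferred_name, concept$synonyms)) {
    key <- name_key(concept$concept_type, nm)
    if (is.null(g$name_index[[key]])) g$name_index[[key]] <- id
  }
  invisible(id)
}

#' Look up a concept by id
#' @param g A `kg` object.
#' @param id Concept identifier.
#' @return The `kg_concept`.
#' @export
kg_concept <- function(g, id) {
  cp <- g$concepts[[id]]
  if (is.null(cp))
    stop_suppkb("unknown concept id '%s'", id, class = "suppkb_unknown_id")
  cp
}

#' Find a concept id by type and name
#'
#' Matches the normalized name against preferred names and synonyms.
#'
#' @param g A `kg` object.
#' @param type Concept type code.
#' @param name Name to look up (normalized internally).
#' @return Concept id, or `NA_character_` if absent.
#' @export
kg_find <- function(g, type, name) {
  g$name_index[[name_key(type, name)]] %||% NA_character_
}

#' All concept ids in a graph
#' @param g A `kg` object.
#' @param type Optional type filter.
#' @return Sorted character vector of ids.
#' @export
kg_concept_ids <- function(g, type = NULL) {
  ids <- names(g$concepts)
  if (!is.null(type)) {
    type <- match.arg(type, concept_types())
    keep <- vapply(g$concepts, function(cp) cp$concept_type == type, logical(1))
    ids <- ids[keep]
  }
  sort(ids)
}

triple_key <- function(head_id, relation, tail_id) {
  paste(head_id, relation, tail_id, sep = "\t")
}

#' Insert a triple, deduplicating
#'
#' The triple <head, relation, tail> is inserted if not already present.
#' Inserting an existing triple merges its sources and attributes into the
#' stored triple (first-seen attribute value wins; the collapse is recorded in
#' the merge log) and returns `FALSE`. Both endpoints must exist and the
#' relation must match [route_relation()] for their types in forward
#' orientation.
#'
#' @param g A `kg` object.
#' @param head_id,tail_id Existing concept ids.
#' @param relation Relation code.
#' @param attributes Named character vector; keys from
#'   [triple_attribute_keys()].
#' @param sources Character vector of source labels.
#' @return `TRUE` if a new triple was inserted, `FALSE` if it merged into an
#'   existing one.
#' @export
kg_add_triple <- function(g, head_id, relation, tail_id,
                          attributes = character(0), sources = character(0)) {
  stopifnot(inherits(g, "kg"))
  relation <- match.arg(relation, relation_types())
  head <- g$concepts[[head_id]]
  tail <- g$concepts[[tail_id]]
  if (is.null(head))
    stop_suppkb("triple head '%s' is not a known concept", head_id,
                class = "suppkb_dangling_endpoint")
  if (is.null(tail))
    stop_suppkb("triple tail '%s' is not a known concept", tail_id,
                class = "suppkb_dangling_endpoint")
  routed <- route_relation(head$concept_type, tail$concept_type)
  if (routed$reversed || routed$relation != relation)
    stop_suppkb(
      "relation '%s' is not valid for (%s, %s); routing requires '%s'%s",
      relation, head$concept_type, tail$concept_type, routed$relation,
      if (routed$reversed) " with swapped endpoints" else "",
      class = "suppkb_schema_error")
  attributes <- unlist(attributes) %||% character(0)
  if (length(attributes) == 0) attributes <- character(0)
  if (length(attributes)) {
    attributes <- vapply(attributes, as.character, character(1))
    bad <- setdiff(names(attributes), triple_attribute_keys())
    if (length(bad))
      stop_suppkb("unknown triple attribute key(s): %s",
                  paste(bad, collapse = ", "), class = "suppkb_schema_error")
  }
  key <- triple_key(head_id, relation, tail_id)
  existing <- g$triples[[key]]
  if (is.null(existing)) {
    g$triples[[key]] <- list(
      head_id = head_id, relation = relation, tail_id = tail_id,
      attributes = attributes, sources = sort(unique(as.character(sources))))
    return(TRUE)
  }
  existing$sources <- sort(unique(c(existing$sources, as.character(sources))))
  add <- setdiff(names(attributes), names(existing$attributes))
  if (length(add))
    existing$attributes <- c(existing$attributes, attributes[add])
  g$triples[[key]] <- existing
  g$merge_log <- c(g$merge_log,
                   sprintf("duplicate triple collapsed: %s [%s] %s (sources: %s)",
                           head_id, relation, tail_id,
                           paste(existing$sources, collapse = ",")))
  FALSE
}

#' Does the graph contain a triple?
#' @param g A `kg` object.
#' @param head_id,relation,tail_id Triple components.
#' @return Logical.
#' @export
kg_has_triple <- function(g, head_id, relation, tail_id) {
  !is.null(g$triples[[triple_key(head_id, relation, tail_id)]])
}

#' Triples incident to a concept
#'
#' All triples in which the concept appears as head or tail, optionally
#' filtered by relation, in deterministic order (relation code, then neighbor
#' id).
#'
#' @param g A `kg` object.
#' @param id Concept id.
#' @param relation Optional relation filter.
#' @param exclude_sources Character vector of source labels; triples whose
#'   provenance is entirely within this set are omitted (source holdout).
#' @return A data.frame with columns `head_id`, `relation`, `tail_id`,
#'   `neighbor_id`, `direction` ("out"/"in"), `sources` (pipe-joined).
#' @export
kg_neighbors <- function(g, id, relation = NULL,
                         exclude_sources = character(0)) {
  kg_concept(g, id)  # lookup error on unknown id
  if (!is.null(relation)) relation <- match.arg(relation, relation_types())
  rows <- Filter(function(t) t$head_id == id || t$tail_id == id, g$triples)
  if (!is.null(relation))
    rows <- Filter(function(t) t$relation == relation, rows)
  if (length(exclude_sources))
    rows <- Filter(function(t)
      length(t$sources) == 0 || length(setdiff(t$sources, exclude_sources)) > 0,
      rows)
  if (length(rows) == 0)
    return(data.frame(head_id = character(0), relation = character(0),
                      tail_id = character(0), neighbor_id = character(0),
                      direction = character(0), sources = character(0),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    head_id = vapply(rows, `[[`, character(1), "head_id"),
    relation = vapply(rows, `[[`, character(1), "relation"),
    tail_id = vapply(rows, `[[`, character(1), "tail_id"),
    stringsAsFactors = FALSE)
  df$direction <- ifelse(df$head_id == id, "out", "in")
  df$neighbor_id <- ifelse(df$direction == "out", df$tail_id, df$head_id)
  df$sources <- vapply(rows, function(t) join_pipe(t$sources), character(1))
  df <- df[order(df$relation, df$neighbor_id), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("head_id", "relation", "tail_id", "neighbor_id", "direction",
         "sources")]
}

#' Number of concepts / triples
#' @param g A `kg` object.
#' @return Integer count.
#' @export
kg_concept_count <- function(g) length(g$concepts)

#' @rdname kg_concept_count
#' @export
kg_triple_count <- function(g) length(g$triples)

#' Triples as a data.frame
#'
#' @param g A `kg` object.
#' @return Data.frame with one row per triple, sorted by (relation, head_id,
#'   tail_id); attribute columns from [triple_attribute_keys()].
#' @export
kg_triples_df <- function(g) {
  akeys <- triple_attribute_keys()
  ts <- g$triples
  df <- data.frame(
    head_id = vapply(ts, `[[`, character(1), "head_id") %||% character(0),
    relation = vapply(ts, `[[`, character(1), "relation") %||% character(0),
    tail_id = vapply(ts, `[[`, character(1), "tail_id") %||% character(0),
    stringsAsFactors = FALSE)
  for (k in akeys)
    df[[k]] <- vapply(ts, function(t) attr_get(t$attributes, k),
                      character(1)) %||% character(0)
  df$sources <- vapply(ts, function(t) join_pipe(t$sources), character(1)) %||%
    character(0)
  df <- df[order(df$relation, df$head_id, df$tail_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

concepts_df <- function(g, type) {
  cps <- Filter(function(cp) cp$concept_type == type, g$concepts)
  akeys <- concept_attribute_keys()
  df <- data.frame(
    idisk_id = vapply(cps, `[[`, character(1), "idisk_id") %||% character(0),
    preferred_name = vapply(cps, `[[`, character(1), "preferred_name") %||%
      character(0),
    synonyms = vapply(cps, function(cp) join_pipe(cp$synonyms), character(1)) %||%
      character(0),
    cui = vapply(cps, `[[`, character(1), "cui") %||% character(0),
    stringsAsFactors = FALSE)
  for (k in akeys)
    df[[k]] <- vapply(cps, function(cp) attr_get(cp$attributes, k),
                      character(1)) %||% character(0)
  df$sources <- vapply(cps, function(cp) join_pipe(cp$sources), character(1)) %||%
    character(0)
  df <- df[order(df$idisk_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export a graph to bulk-import tables
#'
#' Writes one UTF-8 CSV per concept type (`concepts_<TYPE>.csv`) and one per
#' relation type (`relations_<relation>.csv`), with header rows, pipe-joined
#' list fields, and columns compatible with a property-graph bulk importer.
#' An empty graph yields 7 empty concept tables and 6 empty relation tables.
#'
#' @param g A `kg` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
kg_export_bulk <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (ty in concept_types()) {
    f <- file.path(dir, sprintf("concepts_%s.csv", ty))
    utils::write.csv(concepts_df(g, ty), f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  all_t <- kg_triples_df(g)
  for (rel in relation_types()) {
    f <- file.path(dir, sprintf("relations_%s.csv", rel))
    sub <- all_t[all_t$relation == rel,
                 c("head_id", "tail_id", triple_attribute_keys(), "sources"),
                 drop = FALSE]
    utils::write.csv(sub, f, row.names = FALSE, na = "")
    files <- c(files, f)
  }
  invisible(files)
}

read_bulk_csv <- function(f) {
  out <- tryCatch(
    utils::read.csv(f, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = character(0)),
    error = function(e)
      stop_suppkb("malformed bulk file '%s': %s", f, conditionMessage(e),
                  class = "suppkb_parse_error"))
  out
}

#' Import a graph from bulk tables
#'
#' Inverse of [kg_export_bulk()]: `kg_import_bulk(kg_export_bulk(g))`
#' reconstructs a graph equal to `g` (same concepts, triples and attributes).
#'
#' @param dir Directory containing the bulk CSV files.
#' @return A `kg` object.
#' @export
kg_import_bulk <- function(dir) {
  g <- kg_new()
  for (ty in concept_types()) {
    f <- file.path(dir, sprintf("concepts_%s.csv", ty))
    if (!file.exists(f))
      stop_suppkb("missing bulk file '%s'", f, class = "suppkb_parse_error")
    df <- read_bulk_csv(f)
    need <- c("idisk_id", "preferred_name", "synonyms", "cui",
              concept_attribute_keys(), "sources")
    if (!all(need %in% names(df)))
      stop_suppkb("bulk file '%s' lacks required column(s): %s", f,
                  paste(setdiff(need, names(df)), collapse = ", "),
                  class = "suppkb_parse_error")
    for (i in seq_len(nrow(df))) {
      attrs <- unlist(df[i, concept_attribute_keys()])
      attrs <- attrs[nzchar(attrs)]
      kg_add_concept(g, new_concept(
        idisk_id = df$idisk_id[i], concept_type = ty,
        preferred_name = df$preferred_name[i],
        synonyms = split_pipe(df$synonyms[i]),
        cui = if (nzchar(df$cui[i])) df$cui[i] else NA_character_,
        attributes = attrs, sources = split_pipe(df$sources[i])))
    }
  }
  for (rel in relation_types()) {
    f <- file.path(dir, sprintf("relations_%s.csv", rel))
    if (!file.exists(f))
      stop_suppkb("missing bulk file '%s'", f, class = "suppkb_parse_error")
    df <- read_bulk_csv(f)
    for (i in seq_len(nrow(df))) {
      attrs <- unlist(df[i, triple_attribute_keys()])
      attrs <- attrs[nzchar(attrs)]
      kg_add_triple(g, df$head_id[i], rel, df$tail_id[i],
                    attributes = attrs, sources = split_pipe(df$sources[i]))
    }
  }
  g
}

#' Compare two graphs for equality
#'
#' Concept sets (ids, types, names, synonyms, cui, attributes, sources) and
#' triple sets (endpoints, attributes, sources) must match exactly; insertion
#' order and the merge log are ignored.
#'
#' @param a,b `kg` objects.
#' @return Logical.
#' @export
kg_equal <- function(a, b) {
  sort_attrs <- function(x) {
    if (length(x) == 0) return(character(0))
    x[order(names(x))]
  }
  strip <- function(cp) {
    cp <- cp[c("idisk_id", "concept_type", "preferred_name",
               "synonyms", "cui", "attributes", "sources")]
    cp$attributes <- sort_attrs(cp$attributes)
    cp
  }
  ca <- lapply(a$concepts[sort(names(a$concepts))], strip)
  cb <- lapply(b$concepts[sort(names(b$concepts))], strip)
  norm_attrs <- function(ts) lapply(ts, function(t) {
    t$attributes <- sort_attrs(t$attributes)
    t
  })
  ta <- norm_attrs(a$triples[sort(names(a$triples))])
  tb <- norm_attrs(b$triples[sort(names(b$triples))])
  isTRUE(all.equal(ca, cb)) && isTRUE(all.equal(ta, tb))
}

#' Count report over a graph
#'
#' Per-type concept counts, per-relation triple counts, per-attribute counts
#' (concept attributes plus triple attributes), and their sums. Totals are the
#' arithmetic sums of the per-row counts and are invariant under reordering.
#'
#' @param g A `kg` object.
#' @return A list with elements `concepts`, `relations`, `attributes` (named
#'   integer vectors) and `totals` (named numeric vector with entries
#'   `concepts`, `relations`, `attributes`).
#' @export
kg_totals <- function(g) {
  cc <- vapply(concept_types(), function(ty)
    sum(vapply(g$concepts, function(cp) cp$concept_type == ty, logical(1))),
    numeric(1))
  rc <- vapply(relation_types(), function(rel)
    sum(vapply(g$triples, function(t) t$relation == rel, logical(1))),
    numeric(1))
  akeys <- c(concept_attribute_keys(), triple_attribute_keys())
  ac <- vapply(akeys, function(k) {
    sum(vapply(g$concepts, function(cp) k %in% names(cp$attributes),
               logical(1))) +
      sum(vapply(g$triples, function(t) k %in% names(t$attributes),
                 logical(1)))
  }, numeric(1))
  totals_report(cc, rc, ac)
}

#' Arithmetic totals over printed count rows
#'
#' Sums per-row counts into the three table totals; used both by
#' [kg_totals()] and to check a published count table's internal consistency.
#'
#' @param concept_counts,relation_counts,attribute_counts Named numeric
#'   vectors of per-row counts.
#' @return List with per-row vectors and a `totals` vector.
#' @export
totals_report <- function(concept_counts, relation_counts, attribute_counts) {
  list(concepts = concept_counts,
       relations = relation_counts,
       attributes = attribute_counts,
       totals = c(concepts = sum(concept_counts),
                  relations = sum(relation_counts),
                  attributes = sum(attribute_counts)))
}

#' @export
print.kg <- function(x, ...) {
  tt <- kg_totals(x)
  cat(sprintf("<kg> %d concepts, %d triples\n",
              kg_concept_count(x), kg_triple_count(x)))
  nz <- tt$concepts[tt$concepts > 0]
  if (length(nz))
    cat("  concepts:", paste(sprintf("%s=%d", names(nz), nz), collapse = " "),
        "\n")
  nz <- tt$relations[tt$relations > 0]
  if (length(nz))
    cat("  triples: ", paste(sprintf("%s=%d", names(nz), nz), collapse = " "),
        "\n")
  invisible(x)
}
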