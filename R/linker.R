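#' @title Embedding-based entity linking
#' @description
#' Every entity name in the graph (preferred names and synonyms) is embedded
#' into a fixed-dimension unit vector by a pluggable provider; question
#' mentions are embedded with the same provider and linked to the concept
#' with the highest cosine similarity, accepted only when that similarity is
#' at least the threshold (0.75 by default, inclusive). The default provider
#' is a deterministic character-trigram hashing embedder, so indexes are
#' reproducible bit-for-bit and no external service is needed; a real
#' embedding API can be supplied through the same contract.
#' @name linker
NULL

# Deterministic polynomial hash of a string (fixed mixing constants; no RNG).
.str_hash <- function(s) {
  h <- 5381
  for (cc in utf8ToInt(s)) h <- (h * 33 + cc) %% 2147483647
  h
}

#' Deterministic character-trigram hashing embedder
#'
#' Lower-cases the text, pads it with boundary markers, hashes every
#' character trigram onto one of `dim` signed coordinates, and L2-normalizes
#' the result. Identical text always yields an identical vector.
#'
#' @param text Character vector to embed.
#' @param dim Embedding dimension (default 64).
#' @return A numeric matrix, one unit-norm row per input text.
#' @export
trigram_embed <- function(text, dim = 64L) {
  dim <- as.integer(dim)
  out <- matrix(0, nrow = length(text), ncol = dim)
  for (i in seq_along(text)) {
    s <- paste0("#", norm_name(text[[i]]), "#")
    v <- numeric(dim)
    if (nchar(s) >= 3) {
      for (j in seq_len(nchar(s) - 2L)) {
        h <- .str_hash(substr(s, j, j + 2L))
        idx <- (h %% dim) + 1L
        sign <- if ((h %/% dim) %% 2 == 0) 1 else -1
        v[idx] <- v[idx] + sign
      }
    }
    n <- sqrt(sum(v^2))
    if (n > 0) v <- v / n
    out[i, ] <- v
  }
  out
}

#' Make an embedding provider
#'
#' Wraps an embedding function with the fingerprint used to reject
#' mixed-provider indexes.
#'
#' @param embed Function `character vector -> matrix` of row vectors.
#' @param fingerprint Provider identity string.
#' @param dim Embedding dimension.
#' @return A list of class `embedding_provider`.
#' @export
embedding_provider <- function(embed, fingerprint, dim) {
  structure(list(embed = embed, fingerprint = fingerprint,
                 dim = as.integer(dim)),
            class = "embedding_provider")
}

#' The default deterministic provider
#' @param dim Embedding dimension (default 64).
#' @return An `embedding_provider`.
#' @export
default_provider <- function(dim = 64L) {
  embedding_provider(function(text) trigram_embed(text, dim = dim),
                     fingerprint = sprintf("trigram-hash-v1-d%d", dim),
                     dim = dim)
}

#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (|u| |v|)`, in [-1, 1], symmetric.
#'
#' @param u,v Numeric vectors of equal dimension.
#' @return Cosine similarity.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop_suppkb("cosine: dimension mismatch (%d vs %d)", length(u), length(v),
                class = "suppkb_dim_mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_suppkb("cosine similarity is undefined for a zero vector",
                class = "suppkb_zero_vector")
  sum(u * v) / (nu * nv)
}

#' Build the entity vector index for a graph
#'
#' Embeds every concept name — preferred names and, by default, all synonyms
#' (synonyms vote for their concept by maximum similarity at query time).
#'
#' @param g A `kg` object.
#' @param provider An `embedding_provider` (default: the deterministic
#'   trigram embedder).
#' @param include_synonyms Embed synonyms as well as preferred names
#'   (default `TRUE`).
#' @return An object of class `entity_index`: matrix of unit row vectors with
#'   parallel `ids`/`labels`, provider fingerprint, and the provider itself
#'   for query embedding.
#' @export
build_entity_index <- function(g, provider = default_provider(),
                               include_synonyms = TRUE) {
  stopifnot(inherits(provider, "embedding_provider"))
  ids <- character(0); labels <- character(0)
  for (id in kg_concept_ids(g)) {
    cp <- g$concepts[[id]]
    nms <- if (include_synonyms) c(cp$preferred_name, cp$synonyms)
      else cp$preferred_name
    ids <- c(ids, rep(id, length(nms)))
    labels <- c(labels, nms)
  }
  vec <- if (length(labels)) provider$embed(labels)
    else matrix(0, 0, provider$dim)
  structure(list(vectors = vec, ids = ids, labels = labels,
                 fingerprint = provider$fingerprint, dim = provider$dim,
                 provider = provider),
            class = "entity_index")
}

#' Build an index directly from supplied vectors
#'
#' For constructed-vector experiments and tests; rows are normalized to unit
#' length.
#'
#' @param vectors Numeric matrix, one row per entry.
#' @param ids Concept id per row.
#' @param labels Optional name per row.
#' @param provider Provider used for query embedding (optional; linking by
#'   raw query vector needs none).
#' @return An `entity_index`.
#' @export
index_from_vectors <- function(vectors, ids, labels = ids, provider = NULL) {
  stopifnot(nrow(vectors) == length(ids))
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0))
    stop_suppkb("cannot index a zero vector", class = "suppkb_zero_vector")
  structure(list(vectors = vectors / norms, ids = ids, labels = labels,
                 fingerprint = provider$fingerprint %||% "raw-vectors",
                 dim = ncol(vectors), provider = provider),
            class = "entity_index")
}

#' Link a pre-embedded query vector to a concept
#'
#' Exhaustive scan: the concept holding the highest-similarity entry is
#' returned provided that similarity is greater than or equal to the
#' threshold; ties break by lexicographically smallest concept id. Below the
#' threshold the result is a no-match.
#'
#' @param query Numeric query vector (dimension must match the index).
#' @param index An `entity_index`.
#' @param threshold Inclusive acceptance threshold (default 0.75).
#' @return List: `idisk_id` (`NA_character_` on no-match), `similarity`
#'   (best similarity seen, `NA` for an empty index), `matched_name`.
#' @export
link_vector <- function(query, index, threshold = 0.75) {
  stopifnot(inherits(index, "entity_index"))
  if (length(query) != index$dim)
    stop_suppkb("query dimension %d does not match index dimension %d",
                length(query), index$dim, class = "suppkb_dim_mismatch")
  if (length(index$ids) == 0)
    return(list(idisk_id = NA_character_, similarity = NA_real_,
                matched_name = NA_character_))
  qn <- sqrt(sum(query^2))
  if (qn == 0)
    stop_suppkb("cosine similarity is undefined for a zero vector",
                class = "suppkb_zero_vector")
  sims <- as.numeric(index$vectors %*% (query / qn))
  best <- max(sims)
  if (best < threshold)
    return(list(idisk_id = NA_character_, similarity = best,
                matched_name = NA_character_))
  cand <- which(sims == best)
  pick <- cand[order(index$ids[cand], index$labels[cand])][1]
  list(idisk_id = index$ids[pick], similarity = best,
       matched_name = index$labels[pick])
}

#' Link a mention string to a concept
#'
#' Embeds the mention with the index's provider (rejecting a mismatched
#' provider) and delegates to [link_vector()].
#'
#' @param mention Nonempty mention text.
#' @param index An `entity_index` built with a provider.
#' @param threshold Inclusive acceptance threshold (default 0.75).
#' @param provider Optional provider override; its fingerprint must equal the
#'   index fingerprint.
#' @return As [link_vector()].
#' @export
link_mention <- function(mention, index, threshold = 0.75, provider = NULL) {
  if (!is.character(mention) || length(mention) != 1L || !nzchar(trimws(mention)))
    stop_suppkb("mention must be a nonempty string",
                class = "suppkb_bad_input")
  provider <- provider %||% index$provider
  if (is.null(provider))
    stop_suppkb("index carries no provider; embed the mention and use link_vector()",
                class = "suppkb_bad_input")
  if (!identical(provider$fingerprint, index$fingerprint))
    stop_suppkb("provider fingerprint '%s' does not match index '%s'",
                provider$fingerprint, index$fingerprint,
                class = "suppkb_provider_mismatch")
  q <- provider$embed(mention)[1, ]
  link_vector(q, index, threshold = threshold)
}

#' Persist / load an entity vector index
#'
#' Delimited text with a metadata header (dimension, provider fingerprint,
#' default threshold), one row per indexed name.
#'
#' @param index An `entity_index`.
#' @param path File path.
#' @param threshold Default threshold recorded in the header.
#' @return `write_entity_index` returns `path` invisibly;
#'   `read_entity_index` returns an `entity_index` (without a provider; use
#'   [link_vector()] or supply the provider to [link_mention()]).
#' @export
write_entity_index <- function(index, path, threshold = 0.75) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#dim=%d\tfingerprint=%s\tthreshold=%s",
                     index$dim, index$fingerprint,
                     format(threshold, digits = 17)), con)
  df <- data.frame(idisk_id = index$ids, label = index$labels,
                   stringsAsFactors = FALSE)
  vec <- apply(index$vectors, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = "|"))
  df$vector <- as.character(vec)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_entity_index
#' @export
read_entity_index <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[[1]]
  if (!startsWith(hdr, "#dim="))
    stop_suppkb("'%s' is not an entity index file", path,
                class = "suppkb_parse_error")
  fields <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  meta <- vapply(strsplit(fields, "=", fixed = TRUE), `[`, character(1), 2)
  names(meta) <- vapply(strsplit(fields, "=", fixed = TRUE), `[`,
                        character(1), 1)
  df <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  vec <- t(vapply(df$vector,
                  function(s) as.numeric(strsplit(s, "|", fixed = TRUE)[[1]]),
                  numeric(as.integer(meta[["dim"]]))))
  structure(list(vectors = unname(vec), ids = df$idisk_id, labels = df$label,
                 fingerprint = meta[["fingerprint"]],
                 dim = as.integer(meta[["dim"]]), provider = NULL,
                 default_threshold = as.numeric(meta[["threshold"]])),
            class = "entity_index")
}
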