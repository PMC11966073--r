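#' @title Benchmark question generation and bootstrap scoring
#' @description
#' Generates true-or-false and five-option multiple-choice questions from the
#' graph's ingredient-disease (effectiveness) and ingredient-drug
#' (interaction) triples, and scores answering systems with a repeated
#' fixed-size random-sampling (bootstrap) protocol: by default 100 questions
#' per repetition, 10 repetitions, so each system answers 1000 questions per
#' question type.
#' @name qa-eval
NULL

category_relation <- function(category) {
  switch(match.arg(category, c("DS-disease", "DS-drug")),
         "DS-disease" = list(relation = "is_effective_for", type = "DISEASE",
                             tf_stem = "Is it true that %s is effective for %s?",
                             mcq_stem = "Out of the given list, which disease is %s effective for?"),
         "DS-drug" = list(relation = "interacts_with", type = "DRUG",
                          tf_stem = "Is it true that %s interacts with %s?",
                          mcq_stem = "Out of the given list, which drug does %s interact with?"))
}

category_triples <- function(g, relation) {
  Filter(function(t) t$relation == relation, g$triples)
}

#' Generate true-or-false questions from the graph
#'
#' Positive items are phrased from existing triples (gold `"True"`); negative
#' items from uniformly sampled same-type non-edges (gold `"False"`).
#' Seeded and reproducible; when too few distinct non-edges exist, fewer
#' negatives are emitted and the shortfall is reported.
#'
#' @param g A `kg` object with at least one triple in the category.
#' @param category `"DS-disease"` (effectiveness) or `"DS-drug"`
#'   (interactions).
#' @param n Number of items requested.
#' @param seed Integer seed.
#' @param positive_fraction Fraction of items with gold `"True"`
#'   (default 0.5).
#' @return List of QA items; each item is a list with `kind` ("TF"),
#'   `category`, `stem`, `gold` ("True"/"False"), `provenance` (head/tail
#'   ids, relation, `is_edge`). Attribute `"shortfall"` reports missing
#'   negatives, if any.
#' @export
generate_tf <- function(g, category, n, seed, positive_fraction = 0.5) {
  spec <- category_relation(category)
  pool <- category_triples(g, spec$relation)
  if (length(pool) == 0)
    stop_suppkb("graph has no '%s' triples", spec$relation,
                class = "suppkb_empty_pool")
  heads <- sort(unique(vapply(pool, `[[`, character(1), "head_id")))
  tails <- kg_concept_ids(g, spec$type)
  n_pos <- round(n * positive_fraction)
  n_neg <- n - n_pos
  with_seed(seed, {
    pos_idx <- sample(length(pool), n_pos, replace = n_pos > length(pool))
    items <- lapply(pool[pos_idx], function(t) {
      list(kind = "TF", category = category,
           stem = sprintf(spec$tf_stem,
                          kg_concept(g, t$head_id)$preferred_name,
                          kg_concept(g, t$tail_id)$preferred_name),
           gold = "True",
           provenance = list(head_id = t$head_id, relation = spec$relation,
                             tail_id = t$tail_id, is_edge = TRUE))
    })
    negs <- list()
    seen <- character(0)
    tries <- 0L
    max_tries <- 50L * n_neg + 100L
    while (length(negs) < n_neg && tries < max_tries) {
      tries <- tries + 1L
      h <- heads[sample.int(length(heads), 1L)]
      t <- tails[sample.int(length(tails), 1L)]
      key <- paste(h, t, sep = "\t")
      if (key %in% seen || kg_has_triple(g, h, spec$relation, t)) next
      seen <- c(seen, key)
      negs[[length(negs) + 1L]] <- list(
        kind = "TF", category = category,
        stem = sprintf(spec$tf_stem, kg_concept(g, h)$preferred_name,
                       kg_concept(g, t)$preferred_name),
        gold = "False",
        provenance = list(head_id = h, relation = spec$relation,
                          tail_id = t, is_edge = FALSE))
    }
    out <- c(items, negs)
    attr(out, "shortfall") <- n_neg - length(negs)
    out
  })
}

#' Generate multiple-choice questions from the graph
#'
#' Each item asks which entity the subject ingredient is related to, with the
#' true answer, three same-type distractors not linked to the subject, and
#' `"None of the above"` — five options in total. A configurable fraction of
#' items omits the true answer, making `"None of the above"` the gold option.
#' Option order is shuffled per item under the seed; `"None of the above"`
#' stays last. Subjects with too few distractor candidates are skipped.
#'
#' @inheritParams generate_tf
#' @param none_fraction Fraction of items whose gold is
#'   `"None of the above"` (default 0.2).
#' @return List of QA items: `kind` ("MCQ"), `category`, `stem`, `options`
#'   (5), `gold`, `provenance`. Attribute `"skipped"` counts subjects without
#'   enough distractors.
#' @export
generate_mcq <- function(g, category, n, seed, none_fraction = 0.2) {
  spec <- category_relation(category)
  pool <- category_triples(g, spec$relation)
  if (length(pool) == 0)
    stop_suppkb("graph has no '%s' triples", spec$relation,
                class = "suppkb_empty_pool")
  all_tails <- kg_concept_ids(g, spec$type)
  none_label <- "None of the above"
  with_seed(seed, {
    idx <- sample(length(pool), n, replace = n > length(pool))
    items <- list()
    skipped <- 0L
    for (t in pool[idx]) {
      linked <- vapply(
        category_triples(g, spec$relation), function(x)
          if (x$head_id == t$head_id) x$tail_id else NA_character_,
        character(1))
      candidates <- setdiff(all_tails, c(linked[!is.na(linked)], t$tail_id))
      gold_none <- stats::runif(1) < none_fraction
      need <- if (gold_none) 4L else 3L
      if (length(candidates) < need) { skipped <- skipped + 1L; next }
      distract <- sample(candidates, need)
      shown_ids <- if (gold_none) distract else c(t$tail_id, distract)
      shown <- vapply(shown_ids, function(id)
        kg_concept(g, id)$preferred_name, character(1))
      opts <- c(sample(shown), none_label)
      gold <- if (gold_none) none_label
        else kg_concept(g, t$tail_id)$preferred_name
      items[[length(items) + 1L]] <- list(
        kind = "MCQ", category = category,
        stem = sprintf(spec$mcq_stem,
                       kg_concept(g, t$head_id)$preferred_name),
        options = unname(opts), gold = gold,
        provenance = list(head_id = t$head_id, relation = spec$relation,
                          tail_id = t$tail_id, gold_omitted = gold_none))
    }
    attr(items, "skipped") <- skipped
    items
  })
}

#' Serialize / load QA items as JSON lines
#'
#' @param items List of QA items.
#' @param path File path.
#' @return `write_qa_items` returns `path` invisibly; `read_qa_items`
#'   returns the item list.
#' @export
write_qa_items <- function(items, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (it in items)
    writeLines(jsonlite::toJSON(it, auto_unbox = TRUE, null = "null"), con)
  invisible(path)
}

#' @rdname write_qa_items
#' @export
read_qa_items <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"),
         function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Wrap the RAG pipeline as a question-answering system function
#'
#' @param g A `kg` object.
#' @param index An `entity_index` over `g`.
#' @param extractor Optional mention extractor override.
#' @param threshold Linking threshold.
#' @param exclude_sources Source holdout applied at retrieval.
#' @return Function `item -> answer string`, suitable for
#'   [bootstrap_eval()].
#' @export
rag_system <- function(g, index, extractor = NULL, threshold = 0.75,
                       exclude_sources = character(0)) {
  function(item) {
    if (identical(item$kind, "TF"))
      answer_tf(item$stem, g, index, extractor = extractor,
                threshold = threshold,
                exclude_sources = exclude_sources)$answer
    else
      answer_mcq(item$stem, unlist(item$options), g, index,
                 extractor = extractor, threshold = threshold,
                 exclude_sources = exclude_sources)$answer
  }
}

#' Bootstrap accuracy evaluation
#'
#' Draws `sample_size` questions from the pool per repetition (with
#' replacement by default; the draw mode is configurable), scores the system
#' on each draw, and reports the per-repetition accuracy distribution. With
#' the defaults (100 x 10) the system answers 1000 questions per pool.
#'
#' @param system Function `item -> answer string`.
#' @param pool List of QA items.
#' @param sample_size Questions per repetition (default 100).
#' @param reps Repetitions (default 10).
#' @param seed Integer seed.
#' @param replace Sample with replacement (default `TRUE`).
#' @return A `bootstrap_report`: list with `accuracies` (length `reps`),
#'   `mean`, `total_answered`, `by_category` (named accuracy vector over all
#'   answered items).
#' @export
bootstrap_eval <- function(system, pool, sample_size = 100, reps = 10, seed,
                           replace = TRUE) {
  if (length(pool) == 0)
    stop_suppkb("question pool is empty", class = "suppkb_empty_pool")
  if (!replace && sample_size > length(pool))
    stop_suppkb("sample_size exceeds pool for sampling without replacement",
                class = "suppkb_bad_config")
  with_seed(seed, {
    acc <- numeric(reps)
    cat_ok <- list(); cat_n <- list()
    for (r in seq_len(reps)) {
      idx <- sample(length(pool), sample_size, replace = replace)
      correct <- logical(sample_size)
      for (k in seq_along(idx)) {
        it <- pool[[idx[k]]]
        ans <- system(it)
        correct[k] <- identical(ans, it$gold)
        cc <- it$category %||% "uncategorized"
        cat_ok[[cc]] <- (cat_ok[[cc]] %||% 0L) + as.integer(correct[k])
        cat_n[[cc]] <- (cat_n[[cc]] %||% 0L) + 1L
      }
      acc[r] <- mean(correct)
    }
    by_cat <- vapply(names(cat_n), function(cc) cat_ok[[cc]] / cat_n[[cc]],
                     numeric(1))
    structure(list(accuracies = acc, mean = mean(acc),
                   total_answered = as.integer(reps) * as.integer(sample_size),
                   by_category = by_cat),
              class = "bootstrap_report")
  })
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("Bootstrap evaluation: %d questions answered over %d repetitions\n",
              x$total_answered, length(x$accuracies)))
  cat(sprintf("  mean accuracy %.3f (per-rep range %.3f-%.3f)\n",
              x$mean, min(x$accuracies), max(x$accuracies)))
  for (cc in names(x$by_category))
    cat(sprintf("  %s: %.3f\n", cc, x$by_category[[cc]]))
  invisible(x)
}
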