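#' @title Synthetic multi-source fixtures with ground truth
#' @description
#' Generates delimited source files emulating the statistical structure of
#' the real inputs — cross-source entity overlap, synonymy (within-source
#' group ids and cross-source synonym usage under a shared vocabulary
#' identifier), company-address spelling variants, nonsense ingredient-name
#' noise, and duplicated assertions across sources — together with a full
#' ground-truth record of the intended post-integration state. Entity names
#' come from a pronounceable-syllable grammar so string-similarity matchers
#' behave nontrivially. Everything is driven by a single seed and is
#' byte-reproducible.
#'
#' Soundness rule: the first source record of every entity uses its canonical
#' name, and entities without a vocabulary CUI appear under their canonical
#' name in every source; synonym-named cross-source records are emitted only
#' for CUI-covered entities. Ground truth is therefore recoverable under
#' exactly the integration merge rules.
#' @name synth
NULL

#' Synthetic-data specification
#'
#' Counts and rates defining the generated study conditions.
#'
#' @param n_ingredients,n_products,n_diseases,n_drugs,n_symptoms,n_tc,n_soc
#'   Entity counts per type.
#' @param n_assertions Target number of distinct ingredient-object
#'   assertions (at least one per non-ingredient entity is always emitted).
#' @param synonym_rate Probability an entity carries synonym variants.
#' @param cross_source_overlap Probability an entity (or assertion) appears
#'   in a second source.
#' @param cui_coverage Probability an ingredient/disease/drug/symptom entity
#'   has a vocabulary CUI.
#' @param nonsense_noise_rate Nonsense ingredient rows injected per source,
#'   as a fraction of its ingredient rows.
#' @param address_variant_rate Probability a product row spells its company
#'   country as a recorded variant rather than the canonical form.
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_ingredients = 150, n_products = 180,
                       n_diseases = 70, n_drugs = 60, n_symptoms = 40,
                       n_tc = 15, n_soc = 8, n_assertions = 300,
                       synonym_rate = 0.2, cross_source_overlap = 0.3,
                       cui_coverage = 0.8, nonsense_noise_rate = 0.05,
                       address_variant_rate = 0.3, seed = 1L) {
  spec <- list(n_ingredients = n_ingredients, n_products = n_products,
               n_diseases = n_diseases, n_drugs = n_drugs,
               n_symptoms = n_symptoms, n_tc = n_tc, n_soc = n_soc,
               n_assertions = n_assertions, synonym_rate = synonym_rate,
               cross_source_overlap = cross_source_overlap,
               cui_coverage = cui_coverage,
               nonsense_noise_rate = nonsense_noise_rate,
               address_variant_rate = address_variant_rate,
               seed = as.integer(seed))
  counts <- unlist(spec[startsWith(names(spec), "n_")])
  probs <- unlist(spec[c("synonym_rate", "cross_source_overlap",
                         "cui_coverage", "nonsense_noise_rate",
                         "address_variant_rate")])
  if (any(counts < 0)) stop_suppkb("counts must be >= 0",
                                   class = "suppkb_bad_config")
  if (any(probs < 0 | probs > 1))
    stop_suppkb("rates must lie in [0, 1]", class = "suppkb_bad_config")
  structure(spec, class = "synth_spec")
}

# Pronounceable unique names from a syllable grammar.
make_name_factory <- function() {
  onsets <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
              "v", "z", "ch", "th", "br", "gl", "tr")
  vowels <- c("a", "e", "i", "o", "u", "ai", "ou", "ea")
  seen <- new.env(parent = emptyenv())
  function(n_words = 1L) {
    repeat {
      word <- function() {
        k <- sample(2:4, 1)
        s <- paste0(vapply(seq_len(k), function(i)
          paste0(sample(onsets, 1), sample(vowels, 1)), character(1)),
          collapse = "")
        paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
      }
      nm <- paste(vapply(seq_len(n_words), function(i) word(), character(1)),
                  collapse = " ")
      key <- norm_name(nm)
      if (is.null(seen[[key]])) { seen[[key]] <- TRUE; return(nm) }
    }
  }
}

#' Canonical country spellings and their recorded variants
#'
#' The default alias table for company-address unification.
#'
#' @return Named character vector: variant -> canonical.
#' @export
default_alias_table <- function() {
  c("U.S.A." = "United States",
    "USA" = "United States",
    "United States of America" = "United States",
    "U.K." = "United Kingdom",
    "Great Britain" = "United Kingdom",
    "Deutschland" = "Germany")
}

synth_entities <- function(n, type, new_name, spec, cui_counter) {
  covered_type <- type %in% c("DSI", "DISEASE", "DRUG", "SYMPTOM")
  lapply(seq_len(n), function(i) {
    nm <- new_name()
    n_syn <- if (stats::runif(1) < spec$synonym_rate) sample(1:2, 1) else 0L
    syns <- if (n_syn > 0) vapply(seq_len(n_syn), function(j) new_name(),
                                  character(1)) else character(0)
    has_cui <- covered_type && stats::runif(1) < spec$cui_coverage
    cui <- if (has_cui) sprintf("C%07d", cui_counter$bump()) else NA_character_
    list(type = type, name = nm, synonyms = syns, cui = cui)
  })
}

counter <- function() {
  n <- 0L
  list(bump = function() { n <<- n + 1L; n })
}

semantic_type_of <- function(type) {
  c(DSI = "T109", DISEASE = "T047", DRUG = "T121", SYMPTOM = "T184")[[type]]
}

#' Generate the synthetic multi-source fixture set
#'
#' Emits four sources: `srcA` (products + ingredients, purpose/risk/address
#' attributes), `srcB` (products + ingredients with within-source synonym
#' rows sharing a group id), `srcC` (ingredients + assertions with rating
#' text), and `srcD` (a second assertion dialect duplicating a fraction of
#' `srcC`'s assertions, exercising cross-source triple deduplication). Also
#' writes a controlled-vocabulary file covering the CUI-assigned entities, a
#' build configuration (YAML), and the ground truth (JSON).
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with `files` (named paths), `config` (the build
#'   configuration list), `ground_truth` (list: `counts`, `entities`,
#'   `true_triples` data.frame, `noise` counts), and `dir`.
#' @export
synthesize <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, synthesize_impl(spec, dir))
}

synthesize_impl <- function(spec, dir) {
  new_name <- make_name_factory()
  cui_counter <- counter()
  ents <- list(
    DSI = synth_entities(spec$n_ingredients, "DSI", new_name, spec,
                         cui_counter),
    DISEASE = synth_entities(spec$n_diseases, "DISEASE", new_name, spec,
                             cui_counter),
    DRUG = synth_entities(spec$n_drugs, "DRUG", new_name, spec, cui_counter),
    SYMPTOM = synth_entities(spec$n_symptoms, "SYMPTOM", new_name, spec,
                             cui_counter),
    TC = synth_entities(spec$n_tc, "TC", new_name, spec, cui_counter),
    SOC = synth_entities(spec$n_soc, "SOC", new_name, spec, cui_counter))

  countries <- c("United States", "Canada", "United Kingdom", "Germany")
  variant_of <- split(names(default_alias_table()),
                      unname(default_alias_table()))
  companies <- lapply(seq_len(max(6L, spec$n_products %/% 12L)), function(i)
    list(name = paste(new_name(), sample(c("Labs", "Nutrition", "Health",
                                           "Botanicals"), 1)),
         country = sample(countries, 1)))
  forms <- c("Capsules", "Extract", "Complex", "Formula", "Powder")
  products <- lapply(seq_len(spec$n_products), function(i) {
    comp <- companies[[sample(length(companies), 1)]]
    n_ing <- sample(1:4, 1)
    list(name = paste(new_name(), sample(forms, 1)),
         company = comp$name, country = comp$country,
         purpose = paste("Supports", tolower(new_name())),
         risk = paste("Consult a physician if", tolower(new_name())),
         ingredients = vapply(ents$DSI[sample(spec$n_ingredients,
                                              min(n_ing, spec$n_ingredients))],
                              `[[`, character(1), "name"))
  })

  # Source membership: first listed source is the entity's primary source
  # (canonical name there), a second source joins with prob overlap.
  assign_sources <- function(n, pool) lapply(seq_len(n), function(i) {
    first <- sample(pool, 1)
    if (length(pool) > 1 && stats::runif(1) < spec$cross_source_overlap)
      c(first, sample(setdiff(pool, first), 1))
    else first
  })
  dsi_sources <- assign_sources(spec$n_ingredients, c("srcA", "srcB", "srcC"))
  dsp_sources <- assign_sources(spec$n_products, c("srcA", "srcB"))

  # Assertions: cover every non-ingredient entity once, then random extras.
  ratings <- list(DISEASE = c("Effective", "Possibly effective",
                              "Insufficient evidence"),
                  DRUG = c("Major", "Moderate", "Minor"),
                  SYMPTOM = NA, TC = NA, SOC = NA)
  assertion_pairs <- list()
  seen_pairs <- new.env(parent = emptyenv())
  add_pair <- function(dsi_idx, obj_type, obj_idx) {
    key <- paste(dsi_idx, obj_type, obj_idx, sep = "\t")
    if (!is.null(seen_pairs[[key]])) return(FALSE)
    seen_pairs[[key]] <- TRUE
    rate_pool <- ratings[[obj_type]]
    assertion_pairs[[length(assertion_pairs) + 1L]] <<- list(
      dsi_idx = dsi_idx, obj_type = obj_type, obj_idx = obj_idx,
      rating = if (all(is.na(rate_pool))) NA_character_
        else sample(rate_pool, 1),
      dup = stats::runif(1) < spec$cross_source_overlap)
    TRUE
  }
  obj_types <- c("DISEASE", "DRUG", "SYMPTOM", "TC", "SOC")
  for (ty in obj_types)
    for (j in seq_along(ents[[ty]]))
      add_pair(sample(spec$n_ingredients, 1), ty, j)
  tries <- 0L
  while (length(assertion_pairs) < spec$n_assertions && tries < 20000L) {
    tries <- tries + 1L
    ty <- sample(obj_types, 1)
    if (length(ents[[ty]]) == 0) next
    add_pair(sample(spec$n_ingredients, 1), ty,
             sample(length(ents[[ty]]), 1))
  }

  # --- emit source rows -----------------------------------------------------
  pick_listed_name <- function(ent, primary) {
    # Non-primary mentions may use a synonym when the entity carries a CUI.
    if (!primary && !is.na(ent$cui) && length(ent$synonyms) > 0 &&
        stats::runif(1) < 0.5)
      sample(ent$synonyms, 1)
    else ent$name
  }
  ing_rows <- list(srcA = list(), srcB = list(), srcC = list())
  for (i in seq_along(ents$DSI)) {
    ent <- ents$DSI[[i]]
    srcs <- dsi_sources[[i]]
    for (k in seq_along(srcs)) {
      src <- srcs[[k]]
      listed <- pick_listed_name(ent, primary = k == 1L)
      if (src == "srcA") {
        ing_rows$srcA[[length(ing_rows$srcA) + 1L]] <- list(
          entity = i, name = listed, synonyms = "", group_id = "",
          source_material = paste("Derived from", tolower(ent$name)),
          background = "", safety = "", mechanism_of_action = "",
          cui = ent$cui)
      } else if (src == "srcB") {
        gid <- sprintf("G%05d", i)
        ing_rows$srcB[[length(ing_rows$srcB) + 1L]] <- list(
          entity = i, name = listed, synonyms = "", group_id = gid,
          source_material = "", background = "", safety = "",
          mechanism_of_action = "", cui = ent$cui)
        for (syn in ent$synonyms)   # within-source synonym rows, same group
          ing_rows$srcB[[length(ing_rows$srcB) + 1L]] <- list(
            entity = i, name = syn, synonyms = "", group_id = gid,
            source_material = "", background = "", safety = "",
            mechanism_of_action = "", cui = ent$cui)
      } else {
        ing_rows$srcC[[length(ing_rows$srcC) + 1L]] <- list(
          entity = i, name = listed, synonyms = join_pipe(ent$synonyms),
          group_id = "",
          source_material = "",
          background = paste(ent$name, "is a studied supplement ingredient."),
          safety = "Generally well tolerated.",
          mechanism_of_action = paste("Modulates", tolower(new_name()),
                                      "activity."),
          cui = ent$cui)
      }
    }
  }
  noise_names <- c("8", "%", "%.", "3.5", "??", "-", "!!", "09", "...", "4")
  noise_added <- list(srcA = 0L, srcB = 0L, srcC = 0L)
  for (src in names(ing_rows)) {
    n_noise <- round(spec$nonsense_noise_rate * length(ing_rows[[src]]))
    noise_added[[src]] <- n_noise
    for (j in seq_len(n_noise))
      ing_rows[[src]][[length(ing_rows[[src]]) + 1L]] <- list(
        entity = NA_integer_, name = sample(noise_names, 1), synonyms = "",
        group_id = "", source_material = "", background = "", safety = "",
        mechanism_of_action = "", cui = NA_character_)
  }

  prod_rows <- list(srcA = list(), srcB = list())
  spell_country <- function(country) {
    vars <- variant_of[[country]]
    if (!is.null(vars) && stats::runif(1) < spec$address_variant_rate)
      sample(vars, 1)
    else country
  }
  for (i in seq_along(products)) {
    p <- products[[i]]
    for (src in dsp_sources[[i]]) {
      addr <- sprintf("%d Main Street, %s", 100 + (i * 7) %% 900,
                      spell_country(p$country))
      prod_rows[[src]][[length(prod_rows[[src]]) + 1L]] <- list(
        entity = i, product_name = p$name, company_name = p$company,
        company_address = addr,
        purpose = if (src == "srcA") p$purpose else "",
        risk = if (src == "srcA") p$risk else "",
        ingredients = join_pipe(p$ingredients))
    }
  }

  assert_rows <- list(srcC = list(), srcD = list())
  for (ap in assertion_pairs) {
    subj <- ents$DSI[[ap$dsi_idx]]
    obj <- ents[[ap$obj_type]][[ap$obj_idx]]
    cat_label <- c(DISEASE = "disease", DRUG = "drug", SYMPTOM = "symptom",
                   TC = "therapeutic class", SOC = "organ system")[[ap$obj_type]]
    base <- list(entity_subj = ap$dsi_idx, entity_obj = ap$obj_idx,
                 subject_name = subj$name, object_name = obj$name,
                 object_category = cat_label,
                 rating = ap$rating %||% NA_character_,
                 sentence = sprintf("%s is reported in connection with %s.",
                                    subj$name, obj$name),
                 subject_cui = subj$cui, object_cui = obj$cui)
    assert_rows$srcC[[length(assert_rows$srcC) + 1L]] <- base
    if (ap$dup) {
      dup <- base
      if (!is.na(obj$cui) && length(obj$synonyms) > 0 &&
          stats::runif(1) < 0.5)
        dup$object_name <- sample(obj$synonyms, 1)
      assert_rows$srcD[[length(assert_rows$srcD) + 1L]] <- dup
    }
  }

  # --- write files ----------------------------------------------------------
  na_blank <- function(x) ifelse(is.na(x), "", x)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "", fileEncoding = "UTF-8")
    path
  }
  rows_df <- function(rows, cols) {
    if (length(rows) == 0) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                   cols), stringsAsFactors = FALSE)
      return(df)
    }
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(lapply(r[cols], function(v) na_blank(as.character(v))),
                    stringsAsFactors = FALSE, check.names = FALSE)))
    names(df) <- cols
    df
  }
  ing_cols <- c("name", "synonyms", "group_id", "background", "safety",
                "mechanism_of_action", "source_material", "cui")
  prod_cols <- c("product_name", "company_name", "company_address", "purpose",
                 "risk", "ingredients")
  assert_cols <- c("subject_name", "object_name", "object_category", "rating",
                   "sentence", "subject_cui", "object_cui")
  files <- c(
    srcA_products = write_tsv(rows_df(prod_rows$srcA, prod_cols),
                              file.path(dir, "srcA_products.tsv")),
    srcA_ingredients = write_tsv(rows_df(ing_rows$srcA, ing_cols),
                                 file.path(dir, "srcA_ingredients.tsv")),
    srcB_products = write_tsv(rows_df(prod_rows$srcB, prod_cols),
                              file.path(dir, "srcB_products.tsv")),
    srcB_ingredients = write_tsv(rows_df(ing_rows$srcB, ing_cols),
                                 file.path(dir, "srcB_ingredients.tsv")),
    srcC_ingredients = write_tsv(rows_df(ing_rows$srcC, ing_cols),
                                 file.path(dir, "srcC_ingredients.tsv")),
    srcC_assertions = write_tsv(rows_df(assert_rows$srcC, assert_cols),
                                file.path(dir, "srcC_assertions.tsv")),
    srcD_assertions = write_tsv(rows_df(assert_rows$srcD, assert_cols),
                                file.path(dir, "srcD_assertions.tsv")))

  vocab_rows <- list()
  for (ty in c("DSI", "DISEASE", "DRUG", "SYMPTOM"))
    for (ent in ents[[ty]])
      if (!is.na(ent$cui)) {
        st <- semantic_type_of(ty)
        vocab_rows[[length(vocab_rows) + 1L]] <- list(
          cui = ent$cui, term = ent$name, semantic_types = st,
          preferred = "1")
        for (syn in ent$synonyms)
          vocab_rows[[length(vocab_rows) + 1L]] <- list(
            cui = ent$cui, term = syn, semantic_types = st, preferred = "0")
      }
  files["vocabulary"] <- write_tsv(
    rows_df(vocab_rows, c("cui", "term", "semantic_types", "preferred")),
    file.path(dir, "vocabulary.tsv"))

  config <- list(
    seed_order = c("srcA", "srcB", "srcC", "srcD"),
    sources = list(
      list(file = "srcA_products.tsv", dialect = "product", source = "srcA"),
      list(file = "srcA_ingredients.tsv", dialect = "ingredient",
           source = "srcA"),
      list(file = "srcB_products.tsv", dialect = "product", source = "srcB"),
      list(file = "srcB_ingredients.tsv", dialect = "ingredient",
           source = "srcB"),
      list(file = "srcC_ingredients.tsv", dialect = "ingredient",
           source = "srcC"),
      list(file = "srcC_assertions.tsv", dialect = "assertion",
           source = "srcC"),
      list(file = "srcD_assertions.tsv", dialect = "assertion",
           source = "srcD")),
    alias_table = as.list(default_alias_table()),
    vocabulary = "vocabulary.tsv")
  files["config"] <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, files[["config"]])

  # --- ground truth ---------------------------------------------------------
  entity_tbl <- do.call(rbind, lapply(names(ents), function(ty)
    if (length(ents[[ty]]) == 0) NULL else data.frame(
      type = ty,
      name = vapply(ents[[ty]], `[[`, character(1), "name"),
      cui = vapply(ents[[ty]], `[[`, character(1), "cui"),
      synonyms = vapply(ents[[ty]], function(e) join_pipe(e$synonyms),
                        character(1)),
      stringsAsFactors = FALSE)))
  tt <- list()
  for (ap in assertion_pairs)
    tt[[length(tt) + 1L]] <- data.frame(
      head_type = "DSI", head_name = ents$DSI[[ap$dsi_idx]]$name,
      relation = route_relation("DSI", ap$obj_type)$relation,
      tail_type = ap$obj_type,
      tail_name = ents[[ap$obj_type]][[ap$obj_idx]]$name,
      stringsAsFactors = FALSE)
  seen_pi <- new.env(parent = emptyenv())
  for (i in seq_along(products)) {
    p <- products[[i]]
    for (ing in unique(p$ingredients)) {
      key <- paste(i, norm_name(ing), sep = "\t")
      if (!is.null(seen_pi[[key]])) next
      seen_pi[[key]] <- TRUE
      tt[[length(tt) + 1L]] <- data.frame(
        head_type = "DSP", head_name = p$name, relation = "has_ingredient",
        tail_type = "DSI", tail_name = ing, stringsAsFactors = FALSE)
    }
  }
  true_triples <- do.call(rbind, tt)
  counts <- list(DSI = spec$n_ingredients, DSP = spec$n_products,
                 DISEASE = spec$n_diseases, DRUG = spec$n_drugs,
                 SYMPTOM = spec$n_symptoms, TC = spec$n_tc,
                 SOC = spec$n_soc)
  ground_truth <- list(counts = counts, entities = entity_tbl,
                       true_triples = true_triples,
                       noise_rows = noise_added,
                       n_true_triples = nrow(true_triples))
  files["ground_truth"] <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(ground_truth, files[["ground_truth"]],
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  list(files = files, config = config, ground_truth = ground_truth,
       dir = dir)
}
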