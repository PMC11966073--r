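rec <- function(source, names, cui = NA_character_, id = NULL,
                attrs = character(0)) {
  list(source = source, names = names, cui = cui,
       attributes = attrs,
       record_id = id %||% paste0(source, ":", names[[1]]))
}
prod <- function(source, name, company, id = NULL) {
  list(source = source, product_name = name, company_name = company,
       attributes = c(company_name = company),
       record_id = id %||% paste0(source, ":", name))
}

test_that("products merge on (product name, company name)", {
  res <- integrate_entities(
    list(DSP = list(prod("LNHPD", "Fish Oil Caps", "Oceanic Labs"),
                    prod("DSLD", "Fish Oil Caps", "Oceanic Labs"),
                    prod("DSLD", "Fish Oil Caps", "Other Labs"))),
    seed_source_order = c("LNHPD", "DSLD"))
  expect_equal(length(kg_concept_ids(res$kg, "DSP")), 2)
  reasons <- res$ledger$reason
  expect_equal(sum(reasons == "product-name+company"), 1)
  expect_equal(sum(reasons == "new-entity"), 2)
  merged <- kg_concept(res$kg, res$ledger$idisk_id[[1]])
  expect_setequal(merged$sources, c("LNHPD", "DSLD"))
})

test_that("ingredients merge on shared CUI or identical normalized name", {
  res <- integrate_entities(
    list(DSI = list(
      rec("MSKCC", "Coenzyme Q10", cui = "C1"),
      rec("DSLD", "Ubiquinone", cui = "C1"),        # same CUI, new name
      rec("NMCD", "coenzyme  q10"),                 # identical after normalize
      rec("DSLD", "Ginkgo"),
      rec("NMCD", "Ginseng"))),
    seed_source_order = c("MSKCC", "DSLD", "NMCD"))
  dsi <- kg_concept_ids(res$kg, "DSI")
  expect_length(dsi, 3)
  coq <- kg_concept(res$kg, kg_find(res$kg, "DSI", "Coenzyme Q10"))
  expect_true("Ubiquinone" %in% coq$synonyms)
  expect_setequal(res$ledger$reason,
                  c("new-entity", "same-CUI", "identical-name"))
  # no CUIs and different names never merge
  res2 <- integrate_entities(
    list(DSI = list(rec("a", "Ginkgo"), rec("b", "Ginseng"))),
    seed_source_order = c("a", "b"))
  expect_length(kg_concept_ids(res2$kg, "DSI"), 2)
})

test_that("identifiers are deterministic across rebuilds", {
  make <- function() integrate_entities(
    list(DSI = list(rec("s1", "Alpha", cui = "C9"), rec("s2", "Beta"),
                    rec("s1", "Gamma")),
         DISEASE = list(rec("s2", "Delta"))),
    seed_source_order = c("s1", "s2"))
  a <- make(); b <- make()
  expect_identical(a$ledger, b$ledger)
  expect_true(kg_equal(a$kg, b$kg))
  expect_equal(sort(kg_concept_ids(a$kg, "DSI")),
               c("DI0000001", "DI0000002", "DI0000003"))
  # ledger is total: every record mapped
  expect_equal(nrow(a$ledger), 4)
  expect_false(any(is.na(a$ledger$idisk_id)))
})

test_that("seed source initializes the vocabulary before later sources fold in", {
  res <- integrate_entities(
    list(DSI = list(rec("late", "Zeta"), rec("seed", "Alpha"))),
    seed_source_order = c("seed", "late"))
  # the seed-source record founds DI0000001 even though it arrived second
  expect_equal(kg_find(res$kg, "DSI", "Alpha"), "DI0000001")
  expect_equal(kg_find(res$kg, "DSI", "Zeta"), "DI0000002")
  expect_error(integrate_entities(list(), c("a", "a")),
               class = "suppkb_bad_config")
})

test_that("conflicting attributes keep the seed-source value and log", {
  res <- integrate_entities(
    list(DSI = list(
      rec("s2", "Alpha", cui = "C1", attrs = c(background = "later text")),
      rec("s1", "Alpha", cui = "C1", attrs = c(background = "seed text")))),
    seed_source_order = c("s1", "s2"))
  cp <- kg_concept(res$kg, "DI0000001")
  expect_equal(unname(cp$attributes["background"]), "seed text")
  expect_match(res$conflicts, "background")
})

test_that("assertions and product compositions become deduplicated triples", {
  res <- integrate_entities(
    list(DSI = list(rec("m", "Vitamin C"), rec("m", "Zinc"),
                    rec("m", "Echinacea")),
         DISEASE = list(rec("m", "Common cold")),
         DRUG = list(rec("m", "Warfarin")),
         DSP = list(prod("l", "Cold Formula", "Acme", id = "l:p1"))),
    seed_source_order = c("l", "m", "n"))
  g <- res$kg
  asrt <- function(src, subj, obj, cat, rating = NA_character_)
    list(source = src, subject_name = subj, object_name = obj,
         object_category = cat, rating_text = rating)
  assertions <- list(
    asrt("m", "Vitamin C", "Common cold", "DISEASE", "Effective"),
    asrt("n", "Vitamin C", "Common cold", "DISEASE"),   # duplicate
    asrt("m", "Zinc", "Common cold", "DISEASE"),
    asrt("m", "Echinacea", "Warfarin", "DRUG", "Moderate"),
    asrt("m", "Unknowium", "Common cold", "DISEASE"))   # unmappable
  products <- list(list(source = "l", record_id = "l:p1",
                        product_name = "Cold Formula",
                        ingredient_names = c("Vitamin C", "Zinc",
                                             "Echinacea")))
  tl <- build_triples(g, assertions, products, res$ledger)
  expect_equal(tl$n_inserted, 6)   # 3 assertions + 3 ingredient links
  expect_equal(tl$n_merged, 1)
  expect_equal(nrow(tl$skipped), 1)
  expect_match(tl$skipped$name, "Unknowium")
  key <- paste(kg_find(g, "DSI", "Vitamin C"), "is_effective_for",
               kg_find(g, "DISEASE", "Common cold"), sep = "\t")
  t <- g$triples[[key]]
  expect_setequal(t$sources, c("m", "n"))
  expect_equal(unname(t$attributes["effectiveness_rating"]), "Effective")
  drugt <- g$triples[[paste(kg_find(g, "DSI", "Echinacea"), "interacts_with",
                            kg_find(g, "DRUG", "Warfarin"), sep = "\t")]]
  expect_equal(unname(drugt$attributes["interaction_rating"]), "Moderate")
  expect_equal(kg_triple_count(g), 6)
})

test_that("ten assertions with two duplicates yield eight triples", {
  dsis <- lapply(1:4, function(i) rec("m", paste0("Ing", i)))
  diseases <- lapply(1:4, function(i) rec("m", paste0("Dis", i)))
  res <- integrate_entities(list(DSI = dsis, DISEASE = diseases),
                            seed_source_order = "m")
  pairs <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 3), c(3, 3), c(3, 4),
                c(4, 1), c(4, 2), c(1, 1), c(2, 3))  # last two duplicate
  assertions <- lapply(pairs, function(p)
    list(source = "m", subject_name = paste0("Ing", p[1]),
         object_name = paste0("Dis", p[2]), object_category = "DISEASE",
         rating_text = NA_character_))
  tl <- build_triples(res$kg, assertions)
  expect_equal(kg_triple_count(res$kg), 8)
  expect_equal(tl$n_merged, 2)
})

test_that("concept count is bounded by record count with equality iff no merges", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    dup <- runif(1) < 0.5
    recs <- lapply(seq_len(n), function(k)
      rec("s", if (dup && k == n) "Shared name" else rand_name(),
          cui = if (dup && k == 1) NA_character_ else NA_character_,
          id = paste0("s:", k)))
    if (dup) recs[[1]]$names <- "Shared name"
    res <- integrate_entities(list(DSI = recs), seed_source_order = "s")
    n_out <- length(kg_concept_ids(res$kg, "DSI"))
    expect_lte(n_out, n)
    merged_any <- any(res$ledger$reason != "new-entity")
    expect_equal(n_out == n, !merged_any)
  }
})
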