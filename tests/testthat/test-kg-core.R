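test_that("relation routing is a bijection over the six supported pairs", {
  rt <- relation_routing()
  expect_equal(nrow(rt), 6)
  expect_setequal(rt$relation, relation_types())
  expect_false(anyDuplicated(paste(rt$head_type, rt$tail_type)) > 0)
  for (i in seq_len(nrow(rt))) {
    fwd <- route_relation(rt$head_type[i], rt$tail_type[i])
    expect_equal(fwd$relation, rt$relation[i])
    expect_false(fwd$reversed)
    rev <- route_relation(rt$tail_type[i], rt$head_type[i])
    expect_equal(rev$relation, rt$relation[i])
    expect_true(rev$reversed)
  }
})

test_that("routing assigns the documented relations and rejects others", {
  expect_equal(route_relation("DSI", "DISEASE")$relation, "is_effective_for")
  expect_equal(route_relation("DSI", "DRUG")$relation, "interacts_with")
  expect_equal(route_relation("DSP", "DSI")$relation, "has_ingredient")
  expect_equal(route_relation("DSI", "TC")$relation, "has_therapeutic_class")
  expect_equal(route_relation("DSI", "SOC")$relation, "has_adverse_effect_on")
  expect_equal(route_relation("DSI", "SYMPTOM")$relation,
               "has_adverse_reaction")
  err <- tryCatch(route_relation("DISEASE", "DRUG"), error = identity)
  expect_s3_class(err, "suppkb_no_relation")
  expect_match(conditionMessage(err), "DISEASE")
  expect_match(conditionMessage(err), "DRUG")
  expect_error(route_relation("DSI", "DSI"), class = "suppkb_no_relation")
})

test_that("triple insertion deduplicates and merges provenance", {
  g <- demo_kg()
  n0 <- kg_triple_count(g)
  expect_false(kg_add_triple(g, "DI0000001", "is_effective_for", "DD0000001",
                             sources = "NMCD"))
  expect_equal(kg_triple_count(g), n0)
  t <- g$triples[["DI0000001\tis_effective_for\tDD0000001"]]
  expect_setequal(t$sources, c("MSKCC", "NMCD"))
  expect_gt(length(g$merge_log), 0)
  # distinct triple increments the count
  expect_true(kg_add_triple(g, "DI0000002", "interacts_with", "DG0000001",
                            sources = "DSLD"))
  expect_equal(kg_triple_count(g), n0 + 1)
})

test_that("triple insertion validates endpoints and relation schema", {
  g <- demo_kg()
  expect_error(kg_add_triple(g, "DI0000001", "is_effective_for", "DDnope"),
               class = "suppkb_dangling_endpoint")
  expect_error(kg_add_triple(g, "DI0000001", "interacts_with", "DD0000001"),
               class = "suppkb_schema_error")
  # reversed orientation must be rejected, not silently flipped
  expect_error(kg_add_triple(g, "DD0000001", "is_effective_for", "DI0000001"),
               class = "suppkb_schema_error")
})

test_that("triple set stays a set under repeated insertion sequences", {
  set.seed(42)
  g <- demo_kg()
  pool <- list(c("DI0000001", "is_effective_for", "DD0000001"),
               c("DI0000002", "is_effective_for", "DD0000002"),
               c("DI0000003", "interacts_with", "DG0000002"),
               c("DI0000001", "interacts_with", "DG0000001"))
  for (i in 1:50) {
    p <- pool[[sample(4, 1)]]
    kg_add_triple(g, p[1], p[2], p[3], sources = sample(c("a", "b"), 1))
  }
  keys <- names(g$triples)
  expect_equal(length(keys), length(unique(keys)))
  expect_equal(kg_triple_count(g), 12)  # 10 from fixture + 2 new from pool
})

test_that("neighbors are deterministic, filterable, and validated", {
  g <- demo_kg()
  nb <- kg_neighbors(g, "DI0000002", relation = "is_effective_for")
  expect_equal(nrow(nb), 6)
  expect_equal(nb$neighbor_id, sort(nb$neighbor_id))
  expect_true(all(nb$direction == "out"))
  # unfiltered mixed-relation query returns all incident triples
  nb_all <- kg_neighbors(g, "DI0000001")
  expect_equal(nrow(nb_all), 2)
  expect_equal(nb_all$relation, sort(nb_all$relation))
  # isolated node and unknown id
  kg_add_concept(g, new_concept("TC0000001", "TC", "Antioxidants"))
  expect_equal(nrow(kg_neighbors(g, "TC0000001")), 0)
  expect_error(kg_neighbors(g, "ZZ999"), class = "suppkb_unknown_id")
  # incoming direction from the disease side
  nb_in <- kg_neighbors(g, "DD0000001")
  expect_equal(nb_in$direction, "in")
  expect_equal(nb_in$neighbor_id, "DI0000001")
})

test_that("source holdout hides triples whose provenance is fully excluded", {
  g <- demo_kg()
  nb <- kg_neighbors(g, "DI0000001", relation = "is_effective_for",
                     exclude_sources = "MSKCC")
  expect_equal(nrow(nb), 0)
  kg_add_triple(g, "DI0000001", "is_effective_for", "DD0000001",
                sources = "NMCD")
  nb <- kg_neighbors(g, "DI0000001", relation = "is_effective_for",
                     exclude_sources = "MSKCC")
  expect_equal(nrow(nb), 1)
})

test_that("bulk export/import is the identity on demo and empty graphs", {
  d <- withr::local_tempdir()
  g <- demo_kg()
  files <- kg_export_bulk(g, file.path(d, "demo"))
  expect_length(files, 13)
  g2 <- kg_import_bulk(file.path(d, "demo"))
  expect_true(kg_equal(g, g2))
  # empty graph: 7 + 6 empty tables, round trip preserved
  kg_export_bulk(kg_new(), file.path(d, "empty"))
  ge <- kg_import_bulk(file.path(d, "empty"))
  expect_equal(kg_concept_count(ge), 0)
  expect_equal(kg_triple_count(ge), 0)
})

test_that("bulk round trip is the identity on randomized graphs", {
  d <- withr::local_tempdir()
  for (seed in 1:25) {
    g <- random_kg(seed)
    kg_export_bulk(g, d)
    expect_true(kg_equal(g, kg_import_bulk(d)))
  }
})

test_that("hand-written bulk files import as the expected graph", {
  d <- withr::local_tempdir()
  kg_export_bulk(kg_new(), d)  # start from valid empty tables
  writeLines(c(
    "idisk_id,preferred_name,synonyms,cui,company_name,company_address,product_purpose,product_risk,background,safety,mechanism_of_action,source_material,sources",
    "DI0000001,Acacia,Acacia gum extract|Fiber gum acacia,C0000123,,,,,,,,,DSLD",
    "DI0000002,Ginger,,,,,,,,,,,DSLD"),
    file.path(d, "concepts_DSI.csv"))
  writeLines(c(
    "idisk_id,preferred_name,synonyms,cui,company_name,company_address,product_purpose,product_risk,background,safety,mechanism_of_action,source_material,sources",
    "DD0000001,Diarrhea,,,,,,,,,,,MSKCC"),
    file.path(d, "concepts_DISEASE.csv"))
  writeLines(c(
    "head_id,tail_id,interaction_rating,effectiveness_rating,sources",
    "DI0000001,DD0000001,,Possibly effective,MSKCC",
    "DI0000002,DD0000001,,,MSKCC"),
    file.path(d, "relations_is_effective_for.csv"))
  g <- kg_import_bulk(d)
  expect_equal(kg_concept_count(g), 3)
  expect_equal(kg_triple_count(g), 2)
  expect_true(kg_has_triple(g, "DI0000001", "is_effective_for", "DD0000001"))
  cp <- kg_concept(g, "DI0000001")
  expect_setequal(cp$synonyms, c("Acacia gum extract", "Fiber gum acacia"))
  t <- g$triples[["DI0000001\tis_effective_for\tDD0000001"]]
  expect_equal(unname(t$attributes[["effectiveness_rating"]]),
               "Possibly effective")
  # malformed table is reported as a parse error
  writeLines("not,a,valid,header", file.path(d, "concepts_DRUG.csv"))
  expect_error(kg_import_bulk(d), class = "suppkb_parse_error")
})

test_that("count totals are sums of rows and reorder-invariant", {
  g <- demo_kg()
  tt <- kg_totals(g)
  expect_equal(unname(tt$totals["concepts"]), sum(tt$concepts))
  expect_equal(unname(tt$totals["concepts"]), kg_concept_count(g))
  expect_equal(unname(tt$totals["relations"]), kg_triple_count(g))
  empty <- kg_totals(kg_new())
  expect_true(all(empty$totals == 0))
  # invariance: rebuild the same graph with insertions in another order
  d <- withr::local_tempdir()
  kg_export_bulk(g, d)
  g2 <- kg_import_bulk(d)
  expect_equal(kg_totals(g2), tt)
})

test_that("name index covers preferred names and synonyms", {
  g <- demo_kg()
  expect_equal(kg_find(g, "DSI", "Vitamin C"), "DI0000001")
  expect_equal(kg_find(g, "DSI", "ascorbic ACID"), "DI0000001")
  expect_equal(kg_find(g, "DISEASE", "common cold"), "DD0000001")
  expect_true(is.na(kg_find(g, "DRUG", "common cold")))
})

test_that("cypher adapter emits one MERGE per concept and triple", {
  g <- demo_kg()
  st <- kg_cypher_statements(g)
  expect_length(st, kg_concept_count(g) + kg_triple_count(g))
  expect_true(all(grepl("MERGE", st)))
})
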