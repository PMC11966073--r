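test_that("dictionary extractor finds graph names with offsets", {
  g <- demo_kg()
  ex <- dictionary_extractor(g)
  m1 <- ex("Which disease is Omega-3 Fatty Acids effective for?")
  expect_equal(m1$mention, "Omega-3 Fatty Acids")
  expect_equal(substr("Which disease is Omega-3 Fatty Acids effective for?",
                      m1$start, m1$end), "Omega-3 Fatty Acids")
  m2 <- ex("Is it true that Vitamin C is effective for the common cold?")
  expect_setequal(m2$mention, c("Vitamin C", "common cold"))
  expect_equal(nrow(ex("hello")), 0)
})

test_that("question intent resolves to the asked-about concept type", {
  expect_equal(detect_intent("Which disease is X effective for?"), "DISEASE")
  expect_equal(detect_intent("Does X interact with Y?"), "DRUG")
  expect_equal(detect_intent("What are the side effects of X?"), "SYMPTOM")
  expect_equal(detect_intent("Which therapeutic class does X belong to?"),
               "TC")
  expect_true(is.na(detect_intent("Tell me about X")))
})

test_that("query planning routes neighborhoods and edges", {
  g <- demo_kg()
  p1 <- plan_query(g, "DI0000002", "DISEASE")
  expect_equal(p1$kind, "neighborhood")
  expect_equal(p1$relation, "is_effective_for")
  expect_match(p1$cypher, "is_effective_for")
  expect_match(p1$cypher, "DI0000002", fixed = TRUE)
  p2 <- plan_query(g, c("DI0000001", "DD0000001"), "DISEASE")
  expect_equal(p2$kind, "edge")
  expect_equal(p2$relation, "is_effective_for")
  expect_equal(p2$head_id, "DI0000001")
  p3 <- plan_query(g, c("DG0000001", "DI0000003"), "DRUG")
  expect_equal(p3$relation, "interacts_with")
  expect_true(p3$reversed)           # question named the drug first
  expect_equal(p3$head_id, "DI0000003")
  expect_error(plan_query(g, character(0)), class = "suppkb_fallback")
})

test_that("the neighborhood answer lists exactly the six recorded diseases", {
  g <- demo_kg()
  idx <- build_entity_index(g)
  res <- rag_answer("Which disease is Omega-3 Fatty Acids effective for?",
                    g, idx)
  expect_false(res$plan$fallback_used)
  expect_match(res$answer, "are effective for")
  listed <- res$plan$triples$neighbor_id
  expected <- c("Cardiovascular disease", "Lupus", "Cancer", "Depression",
                "High cholesterol", "Atherosclerosis")
  expect_setequal(vapply(listed, function(id) kg_concept(g, id)$preferred_name,
                         character(1)), expected)
  for (d in expected) expect_match(res$answer, d, fixed = TRUE)
  expect_no_match(res$answer, "Common cold")
})

test_that("unlinkable questions fall back and are flagged", {
  g <- demo_kg()
  idx <- build_entity_index(g)
  res <- rag_answer("Which disease is Styrofoamium effective for?", g, idx,
                    extractor = function(q)
                      data.frame(mention = "Styrofoamium", start = 18,
                                 end = 29, stringsAsFactors = FALSE))
  expect_true(res$plan$fallback_used)
  expect_match(res$answer, "not available")
  # empty graph: every question falls back
  ge <- kg_new()
  res2 <- rag_answer("Which disease is Vitamin C effective for?", ge,
                     build_entity_index(ge))
  expect_true(res2$plan$fallback_used)
})

test_that("template answers are grounded: every named entity is retrieved", {
  g <- demo_kg()
  idx <- build_entity_index(g)
  qs <- c("Which disease is Omega-3 Fatty Acids effective for?",
          "Which drug does Ginkgo interact with?",
          "What are the side effects of Ginkgo?")
  for (q in qs) {
    res <- rag_answer(q, g, idx)
    retrieved <- unique(c(res$plan$triples$head_id,
                          res$plan$triples$tail_id))
    retrieved_names <- vapply(retrieved, function(id)
      kg_concept(g, id)$preferred_name, character(1))
    named <- Filter(function(nm) grepl(nm, res$answer, fixed = TRUE),
                    vapply(g$concepts, `[[`, character(1), "preferred_name"))
    expect_true(all(named %in% retrieved_names))
  }
})

test_that("answers are byte-identical across repeated runs", {
  g <- demo_kg()
  idx <- build_entity_index(g)
  q <- "Which disease is Omega-3 Fatty Acids effective for?"
  expect_identical(rag_answer(q, g, idx)$answer, rag_answer(q, g, idx)$answer)
  g2 <- demo_kg()
  expect_identical(rag_answer(q, g2, build_entity_index(g2))$answer,
                   rag_answer(q, g, idx)$answer)
})

test_that("true-or-false answering checks the routed edge", {
  g <- demo_kg()
  idx <- build_entity_index(g)
  tfq <- "Is it true that Vitamin C is effective for the common cold?"
  expect_equal(answer_tf(tfq, g, idx)$answer, "True")
  expect_equal(answer_tf("Is it true that Ginkgo is effective for the common cold?",
                         g, idx)$answer, "False")
  # unlinkable subject: abstain
  res <- answer_tf("Is it true that Unobtainium is effective for gloom?",
                   g, idx,
                   extractor = function(q)
                     data.frame(mention = c("Unobtainium", "gloom"),
                                start = c(1, 2), end = c(3, 4),
                                stringsAsFactors = FALSE))
  expect_equal(res$answer, "ABSTAIN")
})

test_that("holdout of the providing source flips the worked item to False", {
  g <- demo_kg()
  idx <- build_entity_index(g)
  tfq <- "Is it true that Vitamin C is effective for the common cold?"
  expect_equal(answer_tf(tfq, g, idx)$answer, "True")
  expect_equal(answer_tf(tfq, g, idx, exclude_sources = "MSKCC")$answer,
               "False")
  # a triple also carried by another source survives the holdout
  kg_add_triple(g, "DI0000001", "is_effective_for", "DD0000001",
                sources = "NMCD")
  expect_equal(answer_tf(tfq, g, idx, exclude_sources = "MSKCC")$answer,
               "True")
})

test_that("the worked multiple-choice item selects the recorded disease", {
  g <- demo_kg()
  idx <- build_entity_index(g)
  stem <- "Out of the given list, which disease is Vitamin C effective for?"
  options <- c("Bladder stones", "Common cold", "Stroke",
               "Bleeding hemorrhoids", "None of the above")
  expect_equal(answer_mcq(stem, options, g, idx)$answer, "Common cold")
  # with the gold option absent, fall through to "None of the above"
  options2 <- c("Bladder stones", "Stroke", "Bleeding hemorrhoids", "Lupus",
                "None of the above")
  expect_equal(answer_mcq(stem, options2, g, idx)$answer, "None of the above")
  # source holdout removes the evidence: the gold option no longer qualifies
  expect_equal(answer_mcq(stem, options, g, idx,
                          exclude_sources = "MSKCC")$answer,
               "None of the above")
})
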