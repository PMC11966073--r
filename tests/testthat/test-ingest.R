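write_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  f <- file.path(dir, "fixture.tsv")
  writeLines(lines, f)
  f
}

test_that("product rows parse and incomplete rows are rejected with reasons", {
  f <- write_fixture(c(
    "product_name\tcompany_name\tcompany_address\tpurpose\trisk\tingredients",
    "Fish Oil Caps\tOceanic Labs\t12 Bay Rd, U.S.A.\tHeart health\t\tOmega-3 Fatty Acids|Vitamin E",
    "Calm Blend\tHerbal Inc\t\t\t\tChamomile",
    "\tNoName Co\t\t\t\tGinger"))
  res <- read_source(f, "product", "DSLD")
  expect_equal(res$n_parsed, 2)
  expect_equal(res$n_rejected, 1)
  expect_match(res$rejected$reason, "product_name")
  rec <- res$records[[1]]
  expect_equal(rec$source, "DSLD")
  expect_equal(rec$ingredient_names, c("Omega-3 Fatty Acids", "Vitamin E"))
  expect_true(is.na(res$records[[2]]$purpose))
})

test_that("assertion rows map object categories to concept types", {
  f <- write_fixture(c(
    "subject_name\tobject_name\tobject_category\trating\tsentence",
    "Vitamin C\tcommon cold\tdisease\tEffective\tVitamin C is used to prevent and treat the common cold.",
    "Ginkgo\tWarfarin\tdrug\tMajor\t",
    "Ginkgo\tliver\tbody part\t\t"))
  res <- read_source(f, "assertion", "MSKCC")
  expect_equal(res$n_parsed, 2)
  expect_equal(res$n_rejected, 1)
  expect_equal(res$records[[1]]$object_category, "DISEASE")
  expect_equal(res$records[[2]]$object_category, "DRUG")
  expect_match(res$rejected$reason, "body part")
  expect_error(read_source(f, "nope", "x"), class = "suppkb_bad_dialect")
})

test_that("parsed plus rejected always equals the row count", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:12, 1)
    rows <- vapply(seq_len(n), function(i) {
      nm <- if (runif(1) < 0.3) "" else rand_name()
      paste(nm, rand_name(), sep = "\t")
    }, character(1))
    f <- write_fixture(c("name\tsynonyms", rows))
    res <- read_source(f, "ingredient", "src")
    expect_equal(res$n_parsed + res$n_rejected, n)
  }
})

test_that("nonsense-name filter matches the stated predicate exactly", {
  expect_false(clean_ingredient_name("8"))
  expect_false(clean_ingredient_name("%"))
  expect_false(clean_ingredient_name("%."))
  expect_true(clean_ingredient_name("Acacia"))
  expect_true(clean_ingredient_name("B6"))   # length 2, not all-digit
  # brute-force the predicate over a 20-string fixture with an independent
  # character-class scan
  fixture <- c("8", "%", "%.", "a", "B6", "42", "4 2", "  ", "", "x!",
               "St. John's Wort", "Omega-3", "....", "3.5", "-", "Zn",
               "vitamin d", "##", "9%", "Q")
  oracle <- vapply(fixture, function(s) {
    s <- trimws(s)
    if (nchar(s) < 2) return(FALSE)
    chars <- strsplit(s, "")[[1]]
    all_noise <- all(vapply(chars, function(ch)
      grepl("[0-9[:punct:][:space:]]", ch), logical(1)))
    !all_noise
  }, logical(1))
  expect_equal(unname(clean_ingredient_name(fixture)), unname(oracle))
})

test_that("the cleaning filter is a pure, order-independent predicate", {
  set.seed(9)
  pool <- c("8", "Acacia", "%", "Ginger", "42", "St. John's Wort", "-")
  x <- sample(pool, 40, replace = TRUE)
  k1 <- clean_ingredient_name(x)
  expect_equal(clean_ingredient_name(x), k1)        # idempotent/deterministic
  perm <- sample(length(x))
  expect_equal(clean_ingredient_name(x[perm]), k1[perm])  # elementwise
  # extra patterns are configuration
  expect_false(clean_ingredient_name("unknown extract",
                                     extra_patterns = "^unknown"))
})

test_that("field variants unify through the alias table and log pass-throughs", {
  tab <- default_alias_table()
  res <- unify_field_variants(
    c("U.S.A.", "United States of America", "Canada", "United States"), tab)
  expect_equal(res$values, c("United States", "United States", "Canada",
                             "United States"))
  expect_equal(res$unmatched, c("Canada", "United States"))
})

test_that("synonym grouping collapses shared group ids and partitions records", {
  recs <- list(
    list(source = "DSLD", name = "Fiber gum acacia", synonyms = character(0),
         group_id = "G1", cui = NA_character_),
    list(source = "DSLD", name = "Acacia gum extract", synonyms = character(0),
         group_id = "G1", cui = "C0000100"),
    list(source = "DSLD", name = "Acacia", synonyms = character(0),
         group_id = "G1", cui = "C0000100"),
    list(source = "DSLD", name = "Ginger", synonyms = "Zingiber",
         group_id = NA_character_, cui = NA_character_),
    list(source = "DSLD", name = "Ginseng", synonyms = character(0),
         group_id = NA_character_, cui = NA_character_))
  res <- group_synonyms(recs)
  expect_length(res$groups, 3)
  acacia <- res$groups[[1]]
  expect_setequal(acacia$names, c("Fiber gum acacia", "Acacia gum extract",
                                  "Acacia"))
  expect_equal(acacia$cui, "C0000100")
  # groups partition the input
  idx <- sort(unlist(lapply(res$groups, `[[`, "member_idx")))
  expect_equal(idx, seq_along(recs))
  # no-group records form singletons
  res2 <- group_synonyms(recs[4:5])
  expect_length(res2$groups, 2)
})

test_that("conflicting group metadata keeps the first-seen value and logs", {
  recs <- list(
    list(source = "s", name = "A", synonyms = character(0), group_id = "G",
         cui = "C0000001", background = "first"),
    list(source = "s", name = "B", synonyms = character(0), group_id = "G",
         cui = "C0000002", background = "second"))
  res <- group_synonyms(recs)
  expect_length(res$groups, 1)
  expect_equal(res$groups[[1]]$cui, "C0000001")
  expect_equal(unname(res$groups[[1]]$attributes["background"]), "first")
  expect_gte(length(res$conflicts), 2)
})
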