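test_that("build_lexicon indexes synonyms many-to-many and self-registers preferred names", {
  lex <- build_lexicon(data.frame(
    concept_id = c("C1", "C1"), preferred_name = "butyric acid",
    synonym = c("butyrate", "propylformate")))
  expect_equal(lex$index[["butyrate"]], "C1")
  expect_equal(lex$index[["propylformate"]], "C1")
  expect_equal(lex$index[["butyric acid"]], "C1")  # preferred self-registered

  amb <- build_lexicon(data.frame(
    concept_id = c("C1", "C2"), preferred_name = c("alpha", "beta"),
    synonym = c("shared name", "shared name")))
  expect_setequal(amb$index[["shared name"]], c("C1", "C2"))
  expect_equal(lexicon_stats(amb)$ambiguous, "shared name")

  empty <- build_lexicon(data.frame(concept_id = character(0),
                                    preferred_name = character(0),
                                    synonym = character(0)))
  expect_equal(lexicon_stats(empty)$n_concepts, 0L)
  expect_equal(extract_concepts(rec("1", "anything"), empty), character(0))
})

test_that("lexicon hygiene: empty/short/numeric synonyms are dropped with warning", {
  expect_warning(
    lex <- build_lexicon(data.frame(
      concept_id = "C1", preferred_name = "valid name",
      synonym = c("ok synonym", "!", "7", "x"))),
    "dropped")
  expect_null(lex$index[["7"]])
  expect_null(lex$index[["x"]])
  expect_equal(lex$index[["ok synonym"]], "C1")
  expect_error(build_lexicon(data.frame(concept_id = "", preferred_name = "a",
                                        synonym = "b")), "non-empty")
})

test_that("extract_concepts normalizes synonyms to concepts", {
  lex <- tiny_lexicon()
  expect_equal(extract_concepts(rec("1", abstract = "propylformate was elevated"), lex),
               "C1")
  # synonym-invariance: different spellings hit the same concept
  expect_equal(extract_concepts(rec("1", abstract = "Butyrate levels rose"), lex),
               extract_concepts(rec("2", abstract = "BUTYRIC-ACID levels rose"), lex))
  expect_equal(extract_concepts(rec("1"), lex), character(0))
  # matching is token-based, not substring: no firing inside longer words
  lexc <- build_lexicon(data.frame(concept_id = "C9", preferred_name = "choline",
                                   synonym = "choline"))
  expect_equal(extract_concepts(rec("1", abstract = "catecholamine surge"), lexc),
               character(0))
})

test_that("overlapping matches resolve leftmost-longest", {
  lex <- tiny_lexicon()
  # nested shorter synonym suppressed at the same position...
  expect_equal(extract_concepts(
    rec("1", abstract = "trimethylamine n-oxide levels"), lex), "C2")
  # ...but a separate non-overlapping occurrence still counts
  expect_setequal(extract_concepts(
    rec("1", abstract = "trimethylamine n-oxide and free trimethylamine"), lex),
    c("C2", "C3"))
  # cross-check both against the brute-force oracle
  entries <- data.frame(
    concept_id = c("C1", "C1", "C2", "C2", "C3", "C3"),
    preferred_name = c("butyric acid", "butyric acid", "trimethylamine n-oxide",
                       "trimethylamine n-oxide", "trimethylamine", "trimethylamine"),
    synonym = c("butyrate", "propylformate", "tmao", "trimethylamine n-oxide",
                "tma", "trimethylamine"))
  for (txt in c("trimethylamine n-oxide levels",
                "trimethylamine n-oxide and free trimethylamine",
                "tma tmao butyrate")) {
    expect_equal(extract_concepts(rec("1", abstract = txt), lex),
                 oracle_extract(txt, entries), info = txt)
  }
})

test_that("extract_concepts agrees with the brute-force oracle on random cases", {
  set.seed(314)
  for (i in 1:40) {
    case <- random_ner_case(n_synonyms = 25L, n_tokens = 30L)
    lex <- build_lexicon(case$entries)
    got <- extract_concepts(rec("1", abstract = case$text), lex)
    want <- oracle_extract(case$text, case$entries)
    expect_identical(got, want, info = paste("case", i))
  }
})

test_that("compute_df counts documents, not mentions", {
  lex <- tiny_lexicon()
  docs <- list(
    rec("1", abstract = "butyrate butyrate butyrate"),      # mentions collapse
    rec("2", abstract = "propylformate and butyric acid"),  # synonyms collapse
    rec("3", abstract = "tmao only"),
    rec("4", abstract = "nothing relevant"),
    rec("5", abstract = "butyrate and tmao"))
  corp <- corpus(docs)
  cls <- corp[c(2, 5)]
  dft <- compute_df(corp, cls, lex)
  expect_equal(attr(dft, "n_all"), 5L)
  expect_equal(attr(dft, "n_classified"), 2L)
  expect_equal(dft$df[dft$concept_id == "C1"], 3L)
  expect_equal(dft$dfc[dft$concept_id == "C1"], 2L)
  expect_equal(dft$dfc[dft$concept_id == "C2"], 1L)
  # concept never seen is absent
  expect_false("C3" %in% dft$concept_id)
  expect_true(all(dft$dfc <= dft$df))

  # boundary: classified == all -> df == dfc
  dft2 <- compute_df(corp, corp, lex)
  expect_equal(dft2$df, dft2$dfc)
  # concept only in unclassified docs -> dfc 0
  dft3 <- compute_df(corp, corp[4], lex)
  expect_true(all(dft3$dfc == 0L))
  # classified pmid not in the full corpus is a hard error
  expect_error(compute_df(corp, corpus(list(rec("99", "x"))), lex), "99")
})

test_that("adding documents never decreases df/dfc (property)", {
  set.seed(99)
  lex <- tiny_lexicon()
  words <- c("butyrate", "tmao", "tma", "propylformate", "filler", "words")
  docs <- lapply(1:12, function(i)
    rec(as.character(i), abstract = paste(sample(words, 4, TRUE), collapse = " ")))
  corp_small <- corpus(docs[1:8]); corp_big <- corpus(docs)
  cls_small <- corp_small[1:3]; cls_big <- corp_big[1:5]
  a <- compute_df(corp_small, cls_small, lex)
  b <- compute_df(corp_big, cls_big, lex)
  shared <- intersect(a$concept_id, b$concept_id)
  expect_true(all(b$df[match(shared, b$concept_id)] >=
                  a$df[match(shared, a$concept_id)]))
  expect_true(all(b$dfc[match(shared, b$concept_id)] >=
                  a$dfc[match(shared, a$concept_id)]))
})

test_that("lexicon and df tables round-trip through TSV", {
  ents <- data.frame(
    concept_id = c("C1", "C1", "C2", "C3"),
    preferred_name = c("butyric acid", "butyric acid",
                       "trimethylamine n-oxide", "trimethylamine"),
    synonym = c("butyrate", "propylformate", "tmao", "tma"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_entries(ents, p)
  lex <- read_lexicon(p)
  expect_equal(lexicon_stats(lex)$n_concepts, 3L)
  expect_equal(lex$index[["tmao"]], "C2")

  corp <- corpus(list(rec("1", abstract = "butyrate"), rec("2", abstract = "tma")))
  dft <- compute_df(corp, corp[1], lex)
  q <- withr::local_tempfile(fileext = ".tsv")
  write_df_table(dft, q)
  back <- read_df_table(q)
  expect_equal(as.data.frame(back), as.data.frame(dft))
  expect_equal(attr(back, "n_all"), 2L)
  expect_equal(attr(back, "n_classified"), 1L)
})
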