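test_that("the four ranking formulas evaluate correctly, floors included", {
  expect_equal(rank1(7, 100), 7)
  expect_equal(rank1(0, 5), 0)
  expect_equal(rank1(5, 5), 5)

  expect_equal(rank2(10, 30), 0.5)
  expect_equal(rank2(5, 5), 5)      # df == dfc: denominator floored at 1
  expect_equal(rank2(0, 10), 0)

  expect_equal(rank3(10, 110), 10 / log(100))
  expect_equal(rank3(5, 6), 5)      # df - dfc == 1: ln undefined/0, floored
  expect_equal(rank3(5, 7), 5)      # ln(2) < 1: floored at 1
  expect_equal(rank3(0, 100), 0)

  expect_equal(rank4(10, 30), 5)
  expect_equal(rank4(5, 5), 25)
  expect_equal(rank4(1, 1001), 0.001)

  for (f in list(rank1, rank2, rank3, rank4)) {
    expect_error(f(6, 5), "dfc")
    expect_error(f(-1, 5), "non-negative")
  }
})

test_that("rank identity and monotonicity hold over random count pairs", {
  set.seed(20)
  df <- sample(0:5000, 2000, replace = TRUE)
  dfc <- vapply(df, function(d) sample(0:d, 1), integer(1))
  expect_equal(rank4(dfc, df), rank1(dfc, df) * rank2(dfc, df), tolerance = 1e-12)
  # fixed df: non-decreasing in dfc; fixed dfc > 0: rank2-4 non-increasing in df
  for (f in list(rank1, rank2, rank3, rank4)) {
    expect_true(all(diff(f(0:80, rep(80, 81))) >= 0))
  }
  for (f in list(rank2, rank3, rank4)) {
    expect_true(all(diff(f(rep(10, 91), 10:100)) <= 0))
  }
})

make_dft <- function(ids, names, dfc, df, n_all = 10000L, n_cls = 5000L) {
  df_table(data.frame(concept_id = ids, preferred_name = names,
                      df = as.integer(df), dfc = as.integer(dfc),
                      stringsAsFactors = FALSE), n_all, n_cls)
}

test_that("score_table sorts deterministically with the stated tie chain", {
  dft <- make_dft(c("A", "B"), c("alpha", "beta"), dfc = c(10, 2), df = c(30, 4))
  r <- score_table(dft, "rank4")
  expect_s3_class(r, "ranked_list")
  expect_equal(r$preferred_name, c("alpha", "beta"))
  expect_equal(r$score, c(5, 2/2 * 2))
  expect_equal(r$rank, 1:2)

  # identical score and dfc -> alphabetical by preferred name
  tie <- make_dft(c("Z", "Q"), c("zeta", "quin"), dfc = c(4, 4), df = c(8, 8))
  r2 <- score_table(tie, "rank4")
  expect_equal(r2$preferred_name, c("quin", "zeta"))

  # same score, different dfc -> higher dfc first
  t3 <- make_dft(c("A", "B"), c("aa", "bb"), dfc = c(2, 4), df = c(4, 8))
  r3 <- score_table(t3, "rank2")  # both score 1
  expect_equal(r3$preferred_name, c("bb", "aa"))

  # determinism: re-running is identical
  expect_identical(score_table(dft, "rank4"), score_table(dft, "rank4"))

  empty <- make_dft(character(0), character(0), integer(0), integer(0))
  expect_equal(nrow(score_table(empty, "rank1")), 0L)
})

test_that("rank4 ordering equals ordering by rank1 x rank2 on random tables", {
  set.seed(21)
  for (i in 1:20) {
    n <- 30L
    df <- sample(1:500, n, TRUE)
    dfc <- vapply(df, function(d) sample(0:d, 1), integer(1))
    dft <- make_dft(sprintf("C%02d", 1:n), sprintf("name%02d", 1:n), dfc, df)
    r4 <- score_table(dft, "rank4")
    prod_score <- rank1(dft$dfc, dft$df) * rank2(dft$dfc, dft$df)
    ord <- order(-prod_score, -dft$dfc, dft$preferred_name, method = "radix")
    expect_equal(r4$concept_id, dft$concept_id[ord])
    # output is a permutation of the table's concepts
    expect_setequal(r4$concept_id, dft$concept_id)
  }
})

test_that("ranked lists round-trip through TSV", {
  dft <- make_dft(c("A", "B", "C"), c("aa", "bb", "cc"),
                  dfc = c(9, 3, 0), df = c(20, 30, 7))
  r <- score_table(dft, "rank3")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ranked(r, p)
  back <- read_ranked(p)
  expect_equal(back$concept_id, r$concept_id)
  expect_equal(back$score, r$score, tolerance = 1e-12)
})
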