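test_that("prf counts tp/fp/fn and applies the zero conventions", {
  g <- gold_standard(c("a", "b", "e"))
  m <- prf(c("a", "b", "c", "d"), g)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 2/3)
  expect_equal(m$f1, 2 * 0.5 * (2/3) / (0.5 + 2/3))
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 2, 1))

  perfect <- prf(c("a", "b", "e"), g)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  miss <- prf(c("x", "y"), g)
  expect_equal(c(miss$precision, miss$recall, miss$f1), c(0, 0, 0))

  empty <- prf(character(0), g)
  expect_equal(empty$precision, 0)  # stated convention, not NaN

  # gold joins by the shared normalization
  expect_equal(prf("Butyric-Acid", gold_standard("butyric acid"))$tp, 1)
  expect_error(gold_standard(character(0)), "non-empty")
})

test_that("f1_of reproduces the published two-decimal table values", {
  # published precision/recall pairs; F1 recomputed from printed inputs
  expect_equal(round(f1_of(0.014, 0.959), 3), 0.028)
  expect_equal(round(f1_of(0.055, 0.640), 3), 0.101)
  # published table prints 0.092 for this row; rounded inputs give 0.091
  expect_equal(round(f1_of(0.049, 0.674), 3), 0.091)
  expect_equal(f1_of(1, 1), 1)
  expect_equal(f1_of(0, 0), 0)
  expect_error(f1_of(1.2, 0.5), "\\[0, 1\\]")
})

test_that("f1 is bounded by geometric and arithmetic means (property)", {
  set.seed(30)
  p <- runif(200); r <- runif(200)
  h <- f1_of(p, r)
  g <- sqrt(p * r); a <- (p + r) / 2
  expect_true(all(h <= g + 1e-12))
  expect_true(all(g <= a + 1e-12))
  eq <- abs(p - r) < 1e-12
  expect_true(all(abs(h - a)[eq] < 1e-12))
})

ranked_from_names <- function(names, gold_names) {
  n <- length(names)
  structure(data.frame(rank = seq_len(n), concept_id = sprintf("C%03d", seq_len(n)),
                       preferred_name = names, score = rev(seq_len(n)),
                       dfc = rev(seq_len(n)), df = rev(seq_len(n)) * 2L,
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

test_that("precision_at_k matches the published worked ratios", {
  gold20 <- sprintf("m%02d", 1:20)
  # 8 gold members among the top 20 -> 0.4
  names20 <- c(gold20[1:8], sprintf("x%02d", 1:12))
  r <- ranked_from_names(names20, gold20)
  expect_equal(precision_at_k(r, gold_standard(gold20), 20), 0.4)
  # 26 gold among top 100 -> 0.26
  gold30 <- sprintf("m%02d", 1:30)
  names100 <- c(gold30[1:26], sprintf("x%03d", 1:74))
  r100 <- ranked_from_names(names100, gold30)
  expect_equal(precision_at_k(r100, gold_standard(gold30), 100), 0.26)
  # gold superset of ranked -> 1 at any k
  rall <- ranked_from_names(gold20[1:5], gold20)
  expect_equal(precision_at_k(rall, gold_standard(gold20), 3), 1)
  expect_error(precision_at_k(rall, gold_standard(gold20), 6), "between 1 and")
})

test_that("precision at full depth equals set-level precision", {
  set.seed(31)
  names <- sample(c(sprintf("g%02d", 1:15), sprintf("x%02d", 1:35)))
  g <- gold_standard(sprintf("g%02d", 1:15))
  r <- ranked_from_names(names, NULL)
  expect_equal(precision_at_k(r, g, nrow(r)), prf(names, g)$precision)
})

test_that("pr_curve reports precision at minimal depth reaching each cutoff", {
  gold <- gold_standard(sprintf("g%02d", 1:10))
  # perfect ranking: gold occupies the first |gold| positions
  perfect <- ranked_from_names(c(sprintf("g%02d", 1:10), sprintf("x%02d", 1:40)), NULL)
  pc <- pr_curve(perfect, gold)
  expect_equal(nrow(pc), 11L)
  expect_true(all(pc$precision == 1))
  expect_true(all(pc$attained))
  expect_equal(pc$depth, c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10))

  # full containment: recall 1.0 is attained at the depth of the last gold
  # member; when that member sits at full depth, precision = |gold|/|ranked|
  set.seed(32)
  mixed <- ranked_from_names(c(sample(c(sprintf("g%02d", 1:9), sprintf("x%02d", 1:40))),
                               "g10"), NULL)
  pm <- pr_curve(mixed, gold)
  expect_equal(pm$precision[pm$recall_cutoff == 1], 10 / 50)
  expect_equal(pm$depth[pm$recall_cutoff == 1], 50)

  # gold member missing from the list -> unattained flag, full-depth precision
  partial <- ranked_from_names(c(sprintf("g%02d", 1:5), sprintf("x%02d", 1:5)), NULL)
  pp <- pr_curve(partial, gold)
  expect_false(pp$attained[pp$recall_cutoff == 1])
  expect_equal(pp$precision[pp$recall_cutoff == 1], 0.5)

  expect_error(pr_curve(perfect, gold, c(0.5, 0.4)), "strictly increasing")
  expect_error(pr_curve(perfect, gold, c(0, 0.5)), "within")
})

test_that("random permutations give a flat curve near the gold density", {
  set.seed(33)
  gold <- gold_standard(sprintf("g%03d", 1:20))
  names <- c(sprintf("g%03d", 1:20), sprintf("x%03d", 1:180))
  mids <- replicate(40, {
    pc <- pr_curve(ranked_from_names(sample(names), NULL), gold)
    mean(pc$precision[pc$recall_cutoff >= 0.3])
  })
  expect_equal(mean(mids), 0.1, tolerance = 0.2)  # Monte-Carlo band around 20/200
})

test_that("percent_change and fold_enrichment reproduce the published arithmetic", {
  expect_equal(percent_change(0.014, 0.049), 250)
  expect_equal(round(percent_change(0.959, 0.674), 1), -29.7)
  expect_equal(percent_change(0.3, 0.3), 0)
  expect_error(percent_change(0, 1), "positive")

  expect_equal(fold_enrichment(0.1, 0.5), 5)
  expect_equal(fold_enrichment(0.2, 0.2), 1)
  # rounded published inputs give 39.29; the source prints 38.3 from unrounded values
  expect_equal(round(fold_enrichment(0.014, 0.55), 2), 39.29)
  expect_error(fold_enrichment(0, 1), "positive")
})
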