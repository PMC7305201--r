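# Shared fixtures: tiny records/corpora built in code, plus the brute-force
# NER oracle used by the property and acceptance tests.

rec <- function(pmid, title = "", abstract = "", mesh = character(0),
                kw = character(0), chem = character(0)) {
  medline_record(pmid, title, abstract, mesh, kw, chem)
}

tiny_lexicon <- function() {
  build_lexicon(data.frame(
    concept_id = c("C1", "C1", "C2", "C3"),
    preferred_name = c("butyric acid", "butyric acid",
                       "trimethylamine n-oxide", "trimethylamine"),
    synonym = c("butyrate", "propylformate", "tmao", "tma"),
    stringsAsFactors = FALSE))
}

# Brute-force leftmost-longest oracle, independent of the package's scanner:
# enumerate every (synonym, start) token match by explicit comparison, then
# resolve greedily left to right, longest first.
oracle_extract <- function(text, entries) {
  tokens <- strsplit(metabominer::normalize_text(text), " ", fixed = TRUE)[[1L]]
  tokens <- tokens[nzchar(tokens)]
  n <- length(tokens)
  if (n == 0L) return(character(0))
  keys <- metabominer::normalize_text(entries$synonym)
  cand <- list()
  for (r in seq_len(nrow(entries))) {
    st <- strsplit(keys[r], " ", fixed = TRUE)[[1L]]
    L <- length(st)
    if (L == 0L || L > n) next
    for (s in seq_len(n - L + 1L)) {
      if (all(tokens[s:(s + L - 1L)] == st)) {
        cand[[length(cand) + 1L]] <- list(start = s, len = L,
                                          concept = entries$concept_id[r])
      }
    }
  }
  if (!length(cand)) return(character(0))
  starts <- vapply(cand, `[[`, numeric(1), "start")
  lens <- vapply(cand, `[[`, numeric(1), "len")
  found <- character(0)
  pos <- 1L
  while (pos <= n) {
    here <- which(starts == pos)
    if (length(here)) {
      L <- max(lens[here])
      winners <- here[lens[here] == L]
      found <- c(found, vapply(cand[winners], `[[`, character(1), "concept"))
      pos <- pos + L
    } else {
      pos <- pos + 1L
    }
  }
  sort(unique(found))
}

# Random lexicon entries + documents for oracle-equivalence property tests.
# Tokens are drawn from a shared small alphabet so overlaps and nestings are
# frequent (the hard cases for leftmost-longest matching).
random_ner_case <- function(n_synonyms = 50L, n_tokens = 40L,
                            alphabet = sprintf("w%02d", 1:12)) {
  n_concepts <- max(2L, n_synonyms %/% 3L)
  syn_len <- sample(1:3, n_synonyms, replace = TRUE)
  synonyms <- vapply(syn_len, function(L)
    paste(sample(alphabet, L, replace = TRUE), collapse = " "), character(1))
  ids <- sprintf("K%03d", sample.int(n_concepts, n_synonyms, replace = TRUE))
  entries <- data.frame(concept_id = ids, preferred_name = ids,
                        synonym = synonyms, stringsAsFactors = FALSE)
  text <- paste(sample(alphabet, n_tokens, replace = TRUE), collapse = " ")
  list(entries = entries, text = text)
}

small_bundle <- function(seed = 7L, ...) {
  generate_bundle(synthetic_config(n_docs = 300L, n_concepts = 40L,
                                   n_planted = 8L, seed = seed, ...))
}
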