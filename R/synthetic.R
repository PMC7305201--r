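#' Seeded synthetic corpora with planted enrichment
#'
#' The generator emulates the enrichment hypothesis the ranking formulas
#' exploit: a small "planted" subset of the metabolite vocabulary occurs with
#' elevated probability inside classified (microbial-metabolism) documents
#' and at background probability elsewhere, while the rest of the vocabulary
#' occurs at background probability everywhere. Documents are bags of filler
#' words with embedded entity mentions -- enough structure to exercise
#' tokenization and multi-word leftmost-longest matching, no more.
#'
#' Construction guarantees exact self-consistency: every synonym carries a
#' unique base token (multi-word synonyms add a chemical-style suffix never
#' used standalone), and the filler/title vocabulary is disjoint from synonym
#' tokens. Recognition on a generated corpus therefore reproduces the truth
#' manifest's realized df/dfc exactly, and keyword classification recovers
#' the classified subset exactly.
#'
#' @name synthetic
NULL

SIM_FILLERS <- c(
  "the", "of", "and", "in", "study", "analysis", "samples", "patients",
  "dietary", "fiber", "levels", "were", "measured", "elevated", "plasma",
  "serum", "fecal", "cohort", "association", "between", "observed",
  "increase", "decrease", "during", "treatment", "control", "group",
  "subjects", "daily", "intake", "concentration", "profile", "using",
  "mass", "spectrometry", "targeted", "approach", "results", "showed",
  "significant")
SIM_SUFFIXES <- c("acid", "oxide", "sulfate", "ester")

#' Configuration for the synthetic bundle generator
#'
#' Defaults are the stated simulation world used throughout the test suite:
#' 2,000 documents of which 10% are classified, a 200-concept vocabulary with
#' 20 planted "microbial" concepts, per-document occurrence probability 0.3
#' for planted concepts inside classified documents and 0.01 elsewhere.
#'
#' @param n_docs total documents.
#' @param classified_fraction fraction of documents in the classified
#'   (microbial-metabolism) subset, in (0, 1).
#' @param microbial_only_fraction additional fraction of background documents
#'   given a microbial (but not metabolism) keyword, so the two
#'   classification stages differ.
#' @param n_concepts vocabulary size.
#' @param n_planted number of planted concepts (`<= n_concepts`).
#' @param p_signal per-document occurrence probability of a planted concept
#'   inside classified documents.
#' @param p_background occurrence probability elsewhere and for non-planted
#'   concepts; must satisfy `0 <= p_background < p_signal <= 1`.
#' @param synonyms_per_concept synonyms per concept (including the preferred
#'   name).
#' @param multiword_fraction fraction of synonyms rendered as two-token names
#'   to exercise longest-match recognition.
#' @param n_genes,genes_per_chemical shape of the chemical-gene table.
#' @param seed RNG seed for the bundle's single random stream.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_docs = 2000L, classified_fraction = 0.1,
                             microbial_only_fraction = 0.05,
                             n_concepts = 200L, n_planted = 20L,
                             p_signal = 0.3, p_background = 0.01,
                             synonyms_per_concept = 3L,
                             multiword_fraction = 0.3,
                             n_genes = 50L, genes_per_chemical = 3L,
                             seed = 1L) {
  cfg <- list(n_docs = as.integer(n_docs),
              classified_fraction = classified_fraction,
              microbial_only_fraction = microbial_only_fraction,
              n_concepts = as.integer(n_concepts),
              n_planted = as.integer(n_planted),
              p_signal = p_signal, p_background = p_background,
              synonyms_per_concept = as.integer(synonyms_per_concept),
              multiword_fraction = multiword_fraction,
              n_genes = as.integer(n_genes),
              genes_per_chemical = as.integer(genes_per_chemical),
              seed = as.integer(seed))
  with(cfg, {
    if (n_docs < 1L || n_concepts < 1L || n_planted < 0L || n_genes < 0L ||
        genes_per_chemical < 0L || synonyms_per_concept < 1L) {
      stop("all counts must be non-negative (n_docs, n_concepts, synonyms >= 1)")
    }
    if (n_planted > n_concepts) stop("n_planted must not exceed n_concepts")
    if (!(p_background >= 0 && p_background < p_signal && p_signal <= 1)) {
      stop("need 0 <= p_background < p_signal <= 1")
    }
    if (classified_fraction <= 0 || classified_fraction >= 1) {
      stop("classified_fraction must lie in (0, 1)")
    }
    if (microbial_only_fraction < 0 || classified_fraction + microbial_only_fraction > 1) {
      stop("classified_fraction + microbial_only_fraction must not exceed 1")
    }
  })
  structure(cfg, class = "synthetic_config")
}

# pronounceable pseudo-chemical stem; uniqueness comes from the appended id
sim_stem <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  stems <- vapply(seq_len(n), function(i) {
    paste0(sample(cons, 3, TRUE), sample(vow, 3, TRUE), collapse = "")
  }, character(1))
  # never collide with classification keyword prefixes
  bad <- grepl("^(microb|microf|metabol)", stems)
  if (any(bad)) stems[bad] <- paste0("z", stems[bad])
  stems
}

#' Generate a synthetic pipeline bundle
#'
#' @param config a `synthetic_config`.
#' @return list of class `synthetic_bundle` with components `corpus` (full
#'   corpus), `classified_pmids` (truth: the microbial-metabolism subset),
#'   `microbial_pmids` (truth: the stage-1 subset), `lexicon_entries`
#'   (data.frame for [build_lexicon()]), `lexicon` (built), `gold` (planted
#'   preferred names), `chem_gene` (data.frame `chemical`, `gene`, `score`),
#'   `manifest` (data.frame `concept_id`, `preferred_name`, `planted`, `df`,
#'   `dfc` with realized counts), and `config`.
#' @export
generate_bundle <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  nc <- config$n_concepts
  ns <- config$synonyms_per_concept
  cids <- sprintf("C%04d", seq_len(nc))

  # one unique base token per synonym; some synonyms get a suffix token
  n_syn <- nc * ns
  bases <- paste0(sim_stem(n_syn), seq_len(n_syn))
  multi <- stats::runif(n_syn) < config$multiword_fraction
  syn_names <- ifelse(multi, paste(bases, sample(SIM_SUFFIXES, n_syn, TRUE)), bases)
  syn_concept <- rep(seq_len(nc), each = ns)
  syn_by_concept <- split(syn_names, syn_concept)
  pref <- vapply(syn_by_concept, `[`, character(1), 1L)

  lexicon_entries <- data.frame(
    concept_id = cids[syn_concept],
    preferred_name = pref[syn_concept],
    synonym = syn_names,
    stringsAsFactors = FALSE)
  lexicon <- build_lexicon(lexicon_entries)

  planted <- seq_len(config$n_planted)

  nd <- config$n_docs
  n_cls <- max(1L, round(nd * config$classified_fraction))
  n_mic <- round(nd * config$microbial_only_fraction)
  doc_kind <- rep("background", nd)
  picked <- sample.int(nd, n_cls + n_mic)
  doc_kind[picked[seq_len(n_cls)]] <- "classified"
  if (n_mic > 0L) doc_kind[picked[n_cls + seq_len(n_mic)]] <- "microbial_only"

  # occurrence matrix: docs x concepts, Bernoulli per cell
  p <- matrix(config$p_background, nrow = nd, ncol = nc)
  p[doc_kind == "classified", planted] <- config$p_signal
  occ <- matrix(stats::runif(nd * nc), nd, nc) < p

  mic_kw <- c("microbiota", "microbiome", "microflora", "microbial")
  met_kw <- c("metabolites", "metabolism", "metabolic", "metabolome")

  records <- vector("list", nd)
  for (d in seq_len(nd)) {
    kind <- doc_kind[d]
    title_words <- switch(kind,
      classified = c("gut", sample(mic_kw, 1L), "and", sample(met_kw, 1L),
                     "profiling", "in", sample(SIM_FILLERS, 2L)),
      microbial_only = c("gut", sample(mic_kw, 1L), "communities", "in",
                         sample(SIM_FILLERS, 2L)),
      background = c("a", "study", "of", sample(SIM_FILLERS, 4L)))
    present <- which(occ[d, ])
    mentions <- vapply(present, function(ci) {
      sample(syn_by_concept[[ci]], 1L)
    }, character(1))
    units <- c(mentions, sample(SIM_FILLERS, 6L, TRUE))
    abstract <- paste(sample(units), collapse = " ")
    chem_field <- if (length(mentions) && stats::runif(1) < 0.5) {
      mentions[sample.int(length(mentions), 1L)]
    } else character(0)
    records[[d]] <- medline_record(
      pmid = as.character(d),
      title = paste(title_words, collapse = " "),
      abstract = abstract,
      mesh_headings = sample(SIM_FILLERS, 1L),
      keywords = character(0),
      chemicals = chem_field)
  }
  corp <- corpus(records, source_label = sprintf("synthetic seed=%d", config$seed))

  is_cls <- doc_kind == "classified"
  manifest <- data.frame(
    concept_id = cids,
    preferred_name = unname(pref),
    planted = seq_len(nc) %in% planted,
    df = as.integer(colSums(occ)),
    dfc = as.integer(colSums(occ[is_cls, , drop = FALSE])),
    stringsAsFactors = FALSE)

  gold <- unname(pref[planted])

  # chemical-gene table keyed by a random synonym of each planted concept,
  # exercising synonym-based name mapping downstream
  chem_gene <- data.frame(chemical = character(0), gene = character(0),
                          score = integer(0))
  if (config$n_planted > 0L && config$n_genes > 0L && config$genes_per_chemical > 0L) {
    gene_pool <- sprintf("G%03d", seq_len(config$n_genes))
    rows <- lapply(planted, function(ci) {
      data.frame(
        chemical = sample(syn_by_concept[[ci]], 1L),
        gene = sample(gene_pool, min(config$genes_per_chemical, config$n_genes)),
        score = sample(150:999, min(config$genes_per_chemical, config$n_genes), TRUE),
        stringsAsFactors = FALSE)
    })
    chem_gene <- do.call(rbind, rows)
  }

  structure(list(
    corpus = corp,
    classified_pmids = as.character(which(is_cls)),
    microbial_pmids = as.character(which(is_cls | doc_kind == "microbial_only")),
    lexicon_entries = lexicon_entries,
    lexicon = lexicon,
    gold = gold,
    chem_gene = chem_gene,
    manifest = manifest,
    config = config
  ), class = "synthetic_bundle")
}

#' Write a synthetic bundle to a directory
#'
#' Emits `corpus.jsonl`, a MEDLINE-tagged mirror `corpus.medline`,
#' `lexicon.tsv`, `gold.txt`, `chem_gene.tsv`, `truth_manifest.tsv` and
#' `config.json`.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus_jsonl(bundle$corpus, file.path(dir, "corpus.jsonl"))
  write_medline(bundle$corpus, file.path(dir, "corpus.medline"))
  write_lexicon_entries(bundle$lexicon_entries, file.path(dir, "lexicon.tsv"))
  writeLines(bundle$gold, file.path(dir, "gold.txt"))
  utils::write.table(bundle$chem_gene, file.path(dir, "chem_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$manifest, file.path(dir, "truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(bundle$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
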