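#' End-to-end pipeline orchestration
#'
#' `run_pipeline()` composes the stages in the workflow's canonical order --
#' classify (two stages), recognize entities and tabulate document
#' frequencies, rank, evaluate, score genes -- and returns a machine-readable
#' run report. Every number in the report is recomputable from the emitted
#' intermediate files.
#'
#' @param corpus a `corpus` (or path to a `.jsonl` corpus file).
#' @param lexicon a `lexicon` (or path to a lexicon TSV).
#' @param gold a `gold_standard` (or path to a gold list file).
#' @param chem_gene optional `chem_gene_table` (or path to a chemical-gene
#'   TSV); when present, gene scores for the gold metabolites are included.
#' @param fields field subset for classification and recognition.
#' @param match_mode keyword match mode (see [keyword_set()]).
#' @param method ranking method (default `"rank4"`).
#' @param at_k depths for precision at k (entries beyond the ranked-list
#'   length are skipped with a note).
#' @param pr_cutoffs recall cutoffs for the PR curve.
#' @param aliases optional metabolite-chemical alias data.frame (see
#'   [map_metabolites()]).
#' @param out_dir optional directory; when given, intermediate files
#'   (classified subsets, DF table, ranked list, run report JSON) are written
#'   there.
#' @return list of class `run_report`: stage counts, the three evaluation
#'   rows (baseline / microbial / microbial-metabolism), PR points,
#'   precision at k, gene scores, and settings.
#' @export
run_pipeline <- function(corpus, lexicon, gold, chem_gene = NULL,
                         fields = MEDLINE_FIELDS,
                         match_mode = "token-prefix",
                         method = "rank4",
                         at_k = c(20, 50, 70, 100),
                         pr_cutoffs = c(0.05, seq(0.1, 1, by = 0.1)),
                         aliases = NULL,
                         out_dir = NULL) {
  stage <- "setup"
  abort <- function(e) stop("pipeline stage '", stage, "' failed: ",
                            conditionMessage(e), call. = FALSE)
  tryCatch({
    if (is.character(corpus)) corpus <- read_corpus_jsonl(corpus)
    if (is.character(lexicon)) lexicon <- read_lexicon(lexicon)
    if (is.character(gold)) gold <- read_gold(gold)
    if (is.character(chem_gene)) chem_gene <- read_chem_gene(chem_gene)
    stopifnot(inherits(corpus, "corpus"), inherits(lexicon, "lexicon"),
              inherits(gold, "gold_standard"))
  }, error = abort)

  stage <- "classify"
  tryCatch({
    microbial <- classify_corpus(corpus, preset_keywords("microbial", match_mode), fields)
    metabolism <- classify_corpus(microbial, preset_keywords("metabolism", match_mode), fields)
  }, error = abort)

  stage <- "extract"
  tryCatch({
    dft_metab <- compute_df(corpus, metabolism, lexicon, fields)
    # per-stage extracted sets for the three evaluation rows
    ex_all <- dft_metab$concept_id
    ex_microbial <- sort(unique(unlist(lapply(microbial$records, extract_concepts,
                                              lexicon = lexicon, fields = fields))))
    ex_metabolism <- dft_metab$concept_id[dft_metab$dfc > 0L]
  }, error = abort)

  stage <- "rank"
  tryCatch({
    ranked <- score_table(dft_metab, method)
  }, error = abort)

  stage <- "evaluate"
  tryCatch({
    eval_row <- function(approach, n_articles, ids) {
      m <- prf(preferred_names(lexicon, ids), gold)
      c(list(approach = approach, articles = n_articles,
             extracted_metabolites = length(ids)), m)
    }
    evaluation <- list(
      eval_row("baseline_unclassified", length(corpus), ex_all),
      eval_row("classified_microbial", length(microbial), ex_microbial),
      eval_row("classified_microbial_metabolism", length(metabolism), ex_metabolism))
    pr <- pr_curve(ranked, gold, pr_cutoffs)
    at_k_ok <- at_k[at_k >= 1 & at_k <= nrow(ranked)]
    p_at_k <- data.frame(
      k = as.integer(at_k_ok),
      precision = vapply(at_k_ok, function(k) precision_at_k(ranked, gold, k),
                         numeric(1)))
  }, error = abort)

  stage <- "genes"
  gene_scores <- NULL; mapping <- NULL
  if (!is.null(chem_gene)) tryCatch({
    gold_ids <- lexicon$concepts$concept_id[
      normalize_text(lexicon$concepts$preferred_name) %in% gold$members]
    mapping <- map_metabolites(gold_ids, lexicon, chem_gene, aliases)
    gene_scores <- score_genes(mapping$mapped, chem_gene)
  }, error = abort)

  report <- structure(list(
    counts = list(n_all = length(corpus), n_microbial = length(microbial),
                  n_metabolism = length(metabolism),
                  n_concepts_extracted = length(ex_all)),
    evaluation = evaluation,
    pr_curve = pr,
    precision_at_k = p_at_k,
    ranked = ranked,
    df_table = dft_metab,
    subsets = list(microbial = pmids(microbial), metabolism = pmids(metabolism)),
    gene_scores = gene_scores,
    gene_mapping = mapping,
    settings = list(fields = fields, match_mode = match_mode, method = method,
                    at_k = at_k, pr_cutoffs = pr_cutoffs)
  ), class = "run_report")

  if (!is.null(out_dir)) {
    stage <- "write"
    tryCatch({
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_corpus_jsonl(microbial, file.path(out_dir, "microbial.jsonl"))
      write_corpus_jsonl(metabolism, file.path(out_dir, "metabolism.jsonl"))
      write_df_table(dft_metab, file.path(out_dir, "df.tsv"))
      write_ranked(ranked, file.path(out_dir, "ranked.tsv"))
      if (!is.null(gene_scores)) {
        utils::write.table(gene_scores, file.path(out_dir, "gene_scores.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      json <- list(counts = report$counts,
                   evaluation = report$evaluation,
                   pr_curve = report$pr_curve,
                   precision_at_k = report$precision_at_k,
                   settings = report$settings)
      jsonlite::write_json(json, file.path(out_dir, "run_report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }, error = abort)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  corpus: %d records; microbial: %d; microbial-metabolism: %d\n",
              x$counts$n_all, x$counts$n_microbial, x$counts$n_metabolism))
  for (row in x$evaluation) {
    cat(sprintf("  %-32s articles=%-6d extracted=%-5d P=%.3f R=%.3f F1=%.3f\n",
                row$approach, row$articles, row$extracted_metabolites,
                row$precision, row$recall, row$f1))
  }
  if (nrow(x$precision_at_k)) {
    cat("  precision@k:",
        paste(sprintf("%d=%.3f", x$precision_at_k$k, x$precision_at_k$precision),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Export a manual-curation sheet for the top-ranked metabolites
#'
#' One row per top-k concept with its rank, name, counts, score, the
#' semicolon-joined PMIDs of the classified documents containing it, and an
#' empty `curated_label` column for each of two independent curators. The
#' downstream acceptance rule is conjunctive: a metabolite is labeled
#' microbial only if both curators say yes (see [merge_curation()]).
#'
#' @param ranked a `ranked_list`.
#' @param corpus_classified the classified `corpus` the PMIDs are drawn from.
#' @param lexicon the `lexicon` used for extraction.
#' @param top_k number of rows (`0 <= top_k <= nrow(ranked)`).
#' @param path optional TSV output path.
#' @param fields field subset for recognition.
#' @return data.frame (invisibly written to `path` if given).
#' @export
export_curation_sheet <- function(ranked, corpus_classified, lexicon, top_k,
                                  path = NULL, fields = MEDLINE_FIELDS) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(corpus_classified, "corpus"),
            inherits(lexicon, "lexicon"))
  top_k <- as.integer(top_k)
  if (top_k < 0L || top_k > nrow(ranked)) stop("top_k must be between 0 and nrow(ranked)")
  per_doc <- lapply(corpus_classified$records, extract_concepts,
                    lexicon = lexicon, fields = fields)
  ids <- pmids(corpus_classified)
  top <- ranked[seq_len(top_k), , drop = FALSE]
  pmid_col <- vapply(top$concept_id, function(cid) {
    paste(ids[vapply(per_doc, function(s) cid %in% s, logical(1))], collapse = ";")
  }, character(1))
  out <- data.frame(rank = top$rank, preferred_name = top$preferred_name,
                    dfc = top$dfc, df = top$df, score = top$score,
                    pmids = unname(pmid_col),
                    curated_label_1 = character(top_k),
                    curated_label_2 = character(top_k),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(out)
}

#' Merge two curators' labels conjunctively
#'
#' A metabolite counts as curated-microbial only when both curator columns
#' agree `"yes"` (case-insensitive).
#'
#' @param sheet data.frame with columns `preferred_name`, `curated_label_1`,
#'   `curated_label_2` (a filled-in curation sheet).
#' @return character vector of metabolite names both curators accepted.
#' @export
merge_curation <- function(sheet) {
  need <- c("preferred_name", "curated_label_1", "curated_label_2")
  if (!all(need %in% names(sheet))) {
    stop("sheet must have columns: ", paste(need, collapse = ", "))
  }
  yes <- function(x) tolower(trimws(as.character(x))) == "yes"
  sheet$preferred_name[yes(sheet$curated_label_1) & yes(sheet$curated_label_2)]
}
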