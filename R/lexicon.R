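#' Metabolite synonym lexicon and dictionary-based entity recognition
#'
#' The lexicon maps metabolite concepts (e.g., butyric acid) to all their
#' synonyms (butyrate, propylformate, ...). Recognition scans the normalized
#' token sequence of a record and resolves overlapping candidate matches
#' leftmost-longest, so "trimethylamine" does not fire inside
#' "trimethylamine n-oxide". Recognized synonyms are normalized to their
#' concept, which makes a document mentioning "butyrate" and one mentioning
#' "butyric acid" count toward the same concept.
#'
#' @name lexicon_ner
NULL

#' Build a synonym lexicon
#'
#' @param entries data.frame with columns `concept_id`, `preferred_name`,
#'   `synonym` (one synonym per row). Preferred names are self-registered as
#'   synonyms of their own concept, so they need not be repeated as rows.
#' @param min_chars synonyms whose normalized form is shorter than this are
#'   dropped with a warning (default 2: single-character synonyms are lexicon
#'   noise).
#' @param drop_numeric drop purely numeric synonyms (default `TRUE`).
#' @return an object of class `lexicon` with components `concepts`
#'   (data.frame `concept_id`, `preferred_name`), an internal synonym index
#'   keyed by normalized synonym, and `stats` (concept, synonym and mapping
#'   counts, plus the ambiguous synonyms mapping to more than one concept).
#' @examples
#' lex <- build_lexicon(data.frame(
#'   concept_id = "C1", preferred_name = "butyric acid",
#'   synonym = c("butyrate", "propylformate")))
#' lexicon_stats(lex)
#' @export
build_lexicon <- function(entries, min_chars = 2L, drop_numeric = TRUE) {
  if (!is.data.frame(entries)) entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) == 0L) {
    entries <- data.frame(concept_id = character(0), preferred_name = character(0),
                          synonym = character(0))
  }
  need <- c("concept_id", "preferred_name", "synonym")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(as.character(entries$concept_id)))) stop("concept_id must be non-empty")

  # one preferred name per concept (first occurrence wins)
  first <- !duplicated(entries$concept_id)
  concepts <- data.frame(concept_id = as.character(entries$concept_id[first]),
                         preferred_name = as.character(entries$preferred_name[first]),
                         stringsAsFactors = FALSE)
  concepts <- concepts[order(concepts$concept_id), , drop = FALSE]
  rownames(concepts) <- NULL

  # self-register preferred names, then normalize all synonyms
  syn <- data.frame(
    concept_id = c(as.character(entries$concept_id), concepts$concept_id),
    synonym = c(as.character(entries$synonym), concepts$preferred_name),
    stringsAsFactors = FALSE)
  syn$key <- normalize_text(syn$synonym)

  empty <- !nzchar(syn$key)
  short <- !empty & nchar(gsub(" ", "", syn$key, fixed = TRUE)) < min_chars
  numeric_only <- !empty & grepl("^[0-9 ]+$", syn$key)
  drop <- empty | short | (drop_numeric & numeric_only)
  if (any(drop)) {
    warning(sum(drop), " synonym entr", if (sum(drop) == 1L) "y" else "ies",
            " dropped (empty after normalization, below stop-length, or numeric)")
  }
  syn <- syn[!drop, , drop = FALSE]
  syn <- syn[!duplicated(paste(syn$key, syn$concept_id, sep = "\r")), , drop = FALSE]

  index <- new.env(parent = emptyenv(), size = max(16L, nrow(syn)))
  for (i in seq_len(nrow(syn))) {
    k <- syn$key[i]
    index[[k]] <- c(index[[k]], syn$concept_id[i])
  }
  keys <- ls(index, all.names = TRUE)
  n_per_key <- vapply(keys, function(k) length(index[[k]]), integer(1))
  max_len <- if (length(keys)) max(lengths(strsplit(keys, " ", fixed = TRUE))) else 0L

  structure(list(
    concepts = concepts,
    index = index,
    max_len = max_len,
    stats = list(
      n_concepts = nrow(concepts),
      n_synonyms = length(keys),
      n_mappings = nrow(syn),
      ambiguous = sort(keys[n_per_key > 1L])
    )
  ), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<lexicon> %d concepts, %d synonyms, %d synonym=>concept mappings (%d ambiguous)\n",
              s$n_concepts, s$n_synonyms, s$n_mappings, length(s$ambiguous)))
  invisible(x)
}

#' Lexicon summary statistics
#' @param lexicon a `lexicon`.
#' @return list with `n_concepts`, `n_synonyms`, `n_mappings`, `ambiguous`.
#' @export
lexicon_stats <- function(lexicon) {
  stopifnot(inherits(lexicon, "lexicon"))
  lexicon$stats
}

#' Preferred names for concept ids
#' @param lexicon a `lexicon`.
#' @param concept_ids character vector of concept ids.
#' @return character vector of preferred names (NA for unknown ids).
#' @export
preferred_names <- function(lexicon, concept_ids) {
  stopifnot(inherits(lexicon, "lexicon"))
  lexicon$concepts$preferred_name[match(concept_ids, lexicon$concepts$concept_id)]
}

# Greedy leftmost-longest scan over a token vector; returns unique concept ids.
scan_tokens <- function(tokens, lexicon) {
  n <- length(tokens)
  if (n == 0L || lexicon$max_len == 0L) return(character(0))
  idx <- lexicon$index
  maxl <- lexicon$max_len
  hits <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (len in seq.int(min(maxl, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      ids <- idx[[key]]
      if (!is.null(ids)) {
        hits <- c(hits, ids)
        matched <- len
        break
      }
    }
    i <- i + if (matched > 0L) matched else 1L
  }
  sort(unique(hits))
}

#' Recognize metabolite concepts in a record
#'
#' Document-level dictionary NER: returns the set of concept ids whose
#' synonyms occur in the normalized record text as contiguous token
#' sequences. Overlapping candidates are resolved leftmost-longest; an
#' ambiguous synonym contributes all of its concepts; duplicate mentions
#' collapse (document frequency is the unit of counting downstream).
#'
#' @param record a `medline_record`.
#' @param lexicon a `lexicon`.
#' @param fields field subset passed to [record_text()].
#' @return sorted character vector of concept ids (possibly empty).
#' @export
extract_concepts <- function(record, lexicon, fields = MEDLINE_FIELDS) {
  stopifnot(inherits(lexicon, "lexicon"))
  scan_tokens(tokenize(record_text(record, fields)), lexicon)
}

#' Tabulate per-concept document frequencies
#'
#' Counts, for every concept seen at least once in `corpus_all`, the number
#' of documents containing it in the full corpus (`df`) and in the classified
#' subset (`dfc`). A concept is counted once per document regardless of
#' mention count.
#'
#' @param corpus_all full `corpus`.
#' @param corpus_classified classified sub-corpus; its PMIDs must all occur in
#'   `corpus_all`.
#' @param lexicon a `lexicon`.
#' @param fields field subset for recognition.
#' @return a `df_table`: data.frame with columns `concept_id`,
#'   `preferred_name`, `df`, `dfc`, ordered by concept id, with attributes
#'   `n_all` and `n_classified`.
#' @export
compute_df <- function(corpus_all, corpus_classified, lexicon,
                       fields = MEDLINE_FIELDS) {
  stopifnot(inherits(corpus_all, "corpus"), inherits(corpus_classified, "corpus"),
            inherits(lexicon, "lexicon"))
  all_ids <- pmids(corpus_all)
  cls_ids <- pmids(corpus_classified)
  missing <- setdiff(cls_ids, all_ids)
  if (length(missing)) stop("classified pmid absent from full corpus: ", missing[1L])
  cls_set <- cls_ids

  df <- new.env(parent = emptyenv())
  dfc <- new.env(parent = emptyenv())
  for (rec in corpus_all$records) {
    found <- extract_concepts(rec, lexicon, fields)
    in_cls <- rec$pmid %in% cls_set
    for (cid in found) {
      df[[cid]] <- (if (is.null(df[[cid]])) 0L else df[[cid]]) + 1L
      if (in_cls) dfc[[cid]] <- (if (is.null(dfc[[cid]])) 0L else dfc[[cid]]) + 1L
    }
  }
  cids <- sort(ls(df, all.names = TRUE))
  out <- data.frame(
    concept_id = cids,
    preferred_name = preferred_names(lexicon, cids),
    df = vapply(cids, function(k) df[[k]], integer(1)),
    dfc = vapply(cids, function(k) if (is.null(dfc[[k]])) 0L else dfc[[k]], integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  df_table(out, n_all = length(corpus_all), n_classified = length(corpus_classified))
}

#' Construct a document-frequency table
#'
#' @param x data.frame with columns `concept_id`, `preferred_name`, `df`,
#'   `dfc`.
#' @param n_all,n_classified corpus sizes (denominator bookkeeping).
#' @return object of classes `df_table`, `data.frame`.
#' @export
df_table <- function(x, n_all, n_classified) {
  need <- c("concept_id", "preferred_name", "df", "dfc")
  if (!all(need %in% names(x))) stop("df_table needs columns: ", paste(need, collapse = ", "))
  n_all <- as.integer(n_all); n_classified <- as.integer(n_classified)
  if (n_classified > n_all) stop("n_classified must be <= n_all")
  if (any(x$dfc > x$df)) stop("dfc must be <= df for every concept")
  if (any(x$df > n_all)) stop("df must be <= n_all")
  if (any(x$dfc > n_classified)) stop("dfc must be <= n_classified")
  structure(x, n_all = n_all, n_classified = n_classified,
            class = c("df_table", "data.frame"))
}

#' Read / write lexicon and document-frequency TSV files
#'
#' Lexicon file: TSV with header `concept_id  preferred_name  synonym`, one
#' synonym per row. DF table file: TSV `concept_id  preferred_name  df  dfc`
#' with `n_all` / `n_classified` carried in a `# n_all=.. n_classified=..`
#' comment line.
#'
#' @param path file path.
#' @param ... passed to [build_lexicon()].
#' @return `read_lexicon()`: a `lexicon`; writers return `path` invisibly.
#' @export
read_lexicon <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  entries <- utils::read.delim(path, sep = "\t", header = TRUE,
                               colClasses = "character", quote = "",
                               comment.char = "", fileEncoding = "UTF-8")
  build_lexicon(entries, ...)
}

#' @rdname read_lexicon
#' @param entries data.frame with columns `concept_id`, `preferred_name`,
#'   `synonym`.
#' @export
write_lexicon_entries <- function(entries, path) {
  utils::write.table(entries[, c("concept_id", "preferred_name", "synonym")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_lexicon
#' @param x a `df_table`.
#' @export
write_df_table <- function(x, path) {
  stopifnot(inherits(x, "df_table"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# n_all=%d n_classified=%d",
                     attr(x, "n_all"), attr(x, "n_classified")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_lexicon
#' @export
read_df_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^# n_all=(\\d+) n_classified=(\\d+)$", first))[[1L]]
  if (length(m) != 3L) stop("df table missing '# n_all=.. n_classified=..' header")
  x <- utils::read.delim(path, sep = "\t", header = TRUE, skip = 1L,
                         colClasses = c("character", "character", "integer", "integer"),
                         quote = "", fileEncoding = "UTF-8")
  df_table(x, n_all = as.integer(m[2L]), n_classified = as.integer(m[3L]))
}
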