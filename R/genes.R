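#' Metabolite-gene association scoring
#'
#' Prioritized metabolites are joined by name to a chemical-gene association
#' table (the shape of a STITCH export restricted to human genes), and each
#' gene is scored by the number of distinct associated metabolites. Joining
#' is name-based: a metabolite maps if its normalized preferred name, any of
#' its lexicon synonyms, or a user-supplied alias equals a table chemical.
#'
#' @name gene_interactions
NULL

#' Build a chemical-gene table from (chemical, gene) pairs
#'
#' @param pairs data.frame with columns `chemical`, `gene` (an optional
#'   `score` column carries association confidence).
#' @param min_score optional minimum confidence; rows below it are dropped
#'   (default `NULL`: no threshold, matching a plain name join).
#' @return object of class `chem_gene_table`: list mapping normalized
#'   chemical name to its sorted set of gene symbols.
#' @export
chem_gene_table <- function(pairs, min_score = NULL) {
  if (!is.data.frame(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    return(structure(list(genes = list()), class = "chem_gene_table"))
  }
  if (!all(c("chemical", "gene") %in% names(pairs))) {
    stop("pairs must have columns chemical and gene")
  }
  if (!is.null(min_score)) {
    if (is.null(pairs$score)) stop("min_score given but pairs has no score column")
    pairs <- pairs[as.numeric(pairs$score) >= min_score, , drop = FALSE]
  }
  chem <- normalize_text(pairs$chemical)
  gene <- as.character(pairs$gene)
  keep <- nzchar(chem) & nzchar(gene)
  pairs_key <- paste(chem[keep], gene[keep], sep = "\r")
  uniq <- !duplicated(pairs_key)
  genes <- split(gene[keep][uniq], chem[keep][uniq])
  genes <- lapply(genes, function(g) sort(unique(g)))
  structure(list(genes = genes), class = "chem_gene_table")
}

#' @export
print.chem_gene_table <- function(x, ...) {
  cat(sprintf("<chem_gene_table> %d chemicals, %d chemical-gene pairs\n",
              length(x$genes), sum(lengths(x$genes))))
  invisible(x)
}

#' Read a chemical-gene TSV
#'
#' Rows `chemical<TAB>gene[<TAB>score]`, with or without a header line.
#'
#' @param path file path.
#' @param min_score passed to [chem_gene_table()].
#' @return a `chem_gene_table`.
#' @export
read_chem_gene <- function(path, min_score = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) return(chem_gene_table(data.frame()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("row with missing column at line ", bad[1L])
  d <- data.frame(chemical = vapply(parts, `[`, character(1), 1L),
                  gene = vapply(parts, `[`, character(1), 2L),
                  stringsAsFactors = FALSE)
  if (all(lengths(parts) >= 3L)) {
    d$score <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
  }
  # tolerate a header line
  if (tolower(d$chemical[1L]) == "chemical" && tolower(d$gene[1L]) == "gene") {
    d <- d[-1L, , drop = FALSE]
  }
  chem_gene_table(d, min_score = min_score)
}

#' Map metabolite concepts to table chemicals by name
#'
#' A concept maps if its normalized preferred name, any lexicon synonym, or a
#' supplied alias matches a chemical in the table. The paper-style manual
#' mappings (e.g., "butyric acid" to "butyrate") are reproducible either via
#' lexicon synonyms or via the `aliases` data.frame.
#'
#' @param concept_ids character vector of concept ids.
#' @param lexicon the `lexicon` the concepts came from.
#' @param table a `chem_gene_table`.
#' @param aliases optional data.frame with columns `metabolite_name`,
#'   `chemical_name` adding extra name equivalences.
#' @return list with `mapped` (data.frame `concept_id`, `preferred_name`,
#'   `chemical`) and `unmapped` (character vector of concept ids).
#' @export
map_metabolites <- function(concept_ids, lexicon, table, aliases = NULL) {
  stopifnot(inherits(lexicon, "lexicon"), inherits(table, "chem_gene_table"))
  concept_ids <- unique(as.character(concept_ids))
  chems <- names(table$genes)

  alias_map <- list()
  if (!is.null(aliases) && nrow(aliases)) {
    if (!all(c("metabolite_name", "chemical_name") %in% names(aliases))) {
      stop("aliases must have columns metabolite_name and chemical_name")
    }
    alias_map <- split(normalize_text(aliases$chemical_name),
                       normalize_text(aliases$metabolite_name))
  }

  # all names by which each concept is known: synonyms from the index + preferred
  idx_keys <- ls(lexicon$index, all.names = TRUE)
  rows <- list(); unmapped <- character(0)
  for (cid in sort(concept_ids)) {
    pref <- preferred_names(lexicon, cid)
    syns <- idx_keys[vapply(idx_keys, function(k) cid %in% lexicon$index[[k]], logical(1))]
    cand <- unique(c(normalize_text(pref), syns))
    cand <- c(cand, unlist(alias_map[cand], use.names = FALSE))
    hit <- intersect(cand, chems)
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        concept_id = cid, preferred_name = pref, chemical = sort(hit)[1L],
        stringsAsFactors = FALSE)
    } else {
      unmapped <- c(unmapped, cid)
    }
  }
  mapped <- if (length(rows)) do.call(rbind, rows) else
    data.frame(concept_id = character(0), preferred_name = character(0),
               chemical = character(0))
  list(mapped = mapped, unmapped = unmapped)
}

#' Score genes by number of associated mapped metabolites
#'
#' Each gene's score is the count of distinct mapped metabolites whose
#' chemical lists it. Output is sorted score descending, ties by gene symbol
#' ascending.
#'
#' @param mapped data.frame with a `chemical` column (the `mapped` component
#'   of [map_metabolites()]), or a character vector of chemical names.
#' @param table a `chem_gene_table`.
#' @return data.frame with columns `gene`, `score`.
#' @export
score_genes <- function(mapped, table) {
  stopifnot(inherits(table, "chem_gene_table"))
  chems <- if (is.data.frame(mapped)) mapped$chemical else as.character(mapped)
  chems <- unique(normalize_text(chems))
  gene_lists <- table$genes[intersect(chems, names(table$genes))]
  if (!length(gene_lists)) return(data.frame(gene = character(0), score = integer(0)))
  counts <- table(unlist(gene_lists, use.names = FALSE))
  out <- data.frame(gene = names(counts), score = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
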