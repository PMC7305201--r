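#' @title Bibliographic records and corpora
#' @description A `medline_record` holds one bibliographic record with the
#'   five content fields used throughout the pipeline: title, abstract, MeSH
#'   headings, author keywords, and registered substance (chemical) names.
#'   A `corpus` is an ordered collection of records with unique PMIDs.
#' @name medline
NULL

MEDLINE_FIELDS <- c("title", "abstract", "mesh_headings", "keywords", "chemicals")

#' Construct a bibliographic record
#'
#' @param pmid non-empty identifier string.
#' @param title,abstract single strings; may be empty.
#' @param mesh_headings,keywords,chemicals character vectors of terms; may be
#'   empty. `chemicals` carries substance names (registry numbers are not
#'   indexed).
#' @return an object of class `medline_record`.
#' @export
medline_record <- function(pmid, title = "", abstract = "",
                           mesh_headings = character(0),
                           keywords = character(0),
                           chemicals = character(0)) {
  pmid <- as.character(pmid)
  if (length(pmid) != 1L || is.na(pmid) || !nzchar(pmid)) {
    stop("pmid must be a single non-empty string")
  }
  structure(
    list(pmid = pmid,
         title = as.character(title),
         abstract = as.character(abstract),
         mesh_headings = as.character(mesh_headings),
         keywords = as.character(keywords),
         chemicals = as.character(chemicals)),
    class = "medline_record"
  )
}

#' Construct a corpus of records
#'
#' @param records list of `medline_record` objects.
#' @param source_label free-text label describing provenance.
#' @return an object of class `corpus`.
#' @export
corpus <- function(records = list(), source_label = "") {
  if (!all(vapply(records, inherits, logical(1), "medline_record"))) {
    stop("all elements of records must be medline_record objects")
  }
  ids <- vapply(records, `[[`, character(1), "pmid")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate PMID in corpus: ", dup[1L])
  names(records) <- ids
  structure(list(records = records, source_label = as.character(source_label)),
            class = "corpus")
}

#' @export
length.corpus <- function(x) length(x$records)

#' @export
`[.corpus` <- function(x, i) corpus(unname(x$records[i]), x$source_label)

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d record(s)%s\n", length(x),
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  invisible(x)
}

#' PMIDs of a corpus, in record order
#' @param x a `corpus`.
#' @return character vector.
#' @export
pmids <- function(x) {
  stopifnot(inherits(x, "corpus"))
  unname(vapply(x$records, `[[`, character(1), "pmid"))
}

#' Assemble the matchable text of a record
#'
#' Joins the selected fields with single spaces and applies the shared
#' normalization ([normalize_text()]). This is the text that both the keyword
#' classifier and the entity recognizer see.
#'
#' @param record a `medline_record`.
#' @param fields non-empty subset of
#'   `c("title","abstract","mesh_headings","keywords","chemicals")`.
#' @return a single normalized string (possibly `""`).
#' @export
record_text <- function(record, fields = MEDLINE_FIELDS) {
  stopifnot(inherits(record, "medline_record"))
  bad <- setdiff(fields, MEDLINE_FIELDS)
  if (length(bad)) stop("unknown field name(s): ", paste(bad, collapse = ", "))
  if (!length(fields)) stop("fields must be a non-empty subset of the five field names")
  parts <- unlist(record[fields], use.names = FALSE)
  normalize_text(paste(parts[nzchar(parts)], collapse = " "))
}

#' Read a MEDLINE tagged-format export
#'
#' Parses the standard PubMed "MEDLINE" text export: a 1-4 character tag
#' padded to four columns, `"- "`, the value, with continuation lines
#' indented by spaces. Blocks begin at a `PMID` tag. Recognized tags:
#' `TI` (title), `AB` (abstract), `MH` (MeSH heading), `OT` (keyword),
#' `RN` / `NM` (chemical substance). Unknown tags are ignored.
#'
#' @param path file path.
#' @param source_label label stored on the returned corpus; defaults to the
#'   file name.
#' @return a `corpus`.
#' @export
read_medline <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tag_re <- "^([A-Z0-9]{1,4}) *- (.*)$"

  tags <- character(0); vals <- character(0)
  blocks <- list()
  flush_field <- function() {}
  cur <- NULL; cur_start <- NA_integer_
  records <- list()

  finish <- function(cur) {
    if (is.null(cur)) return(NULL)
    medline_record(
      pmid = cur$pmid,
      title = paste(cur$TI, collapse = " "),
      abstract = paste(cur$AB, collapse = " "),
      mesh_headings = cur$MH,
      keywords = cur$OT,
      chemicals = cur$CHEM
    )
  }
  new_block <- function(pmid) {
    list(pmid = pmid, TI = character(0), AB = character(0),
         MH = character(0), OT = character(0), CHEM = character(0))
  }
  last_tag <- NA_character_

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { last_tag <- NA_character_; next }
    if (grepl(tag_re, ln)) {
      m <- regmatches(ln, regexec(tag_re, ln))[[1L]]
      tag <- m[2L]; val <- m[3L]
      if (tag == "PMID") {
        rec <- finish(cur)
        if (!is.null(rec)) records[[length(records) + 1L]] <- rec
        cur <- new_block(trimws(val))
        last_tag <- NA_character_
        next
      }
      if (is.null(cur)) stop("malformed block: tag before any PMID at line ", i)
      last_tag <- tag
      if (tag %in% c("TI", "AB")) {
        cur[[tag]] <- c(cur[[tag]], val)
      } else if (tag == "MH") {
        cur$MH <- c(cur$MH, val)
      } else if (tag == "OT") {
        cur$OT <- c(cur$OT, val)
      } else if (tag %in% c("RN", "NM")) {
        cur$CHEM <- c(cur$CHEM, val)
      } else {
        last_tag <- NA_character_  # unknown tag: ignore its continuations too
      }
    } else if (grepl("^ +", ln)) {
      # continuation of the previous value line
      if (is.null(cur)) stop("malformed block: continuation before any PMID at line ", i)
      if (!is.na(last_tag)) {
        n <- length(cur[[if (last_tag %in% c("RN", "NM")) "CHEM" else last_tag]])
        key <- if (last_tag %in% c("RN", "NM")) "CHEM" else last_tag
        cur[[key]][n] <- paste(cur[[key]][n], trimws(ln))
      }
    } else {
      stop("malformed line ", i, ": ", ln)
    }
  }
  rec <- finish(cur)
  if (!is.null(rec)) records[[length(records) + 1L]] <- rec

  ids <- vapply(records, `[[`, character(1), "pmid")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate PMID in file: ", dup[1L])
  corpus(records, source_label)
}

#' Write a corpus in MEDLINE tagged format
#'
#' @param x a `corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in x$records) {
    out <- c(sprintf("PMID- %s", rec$pmid))
    if (nzchar(rec$title))    out <- c(out, sprintf("TI  - %s", rec$title))
    if (nzchar(rec$abstract)) out <- c(out, sprintf("AB  - %s", rec$abstract))
    out <- c(out, sprintf("MH  - %s", rec$mesh_headings))
    out <- c(out, sprintf("OT  - %s", rec$keywords))
    out <- c(out, sprintf("NM  - %s", rec$chemicals))
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Read / write the JSON-lines canonical corpus format
#'
#' One JSON object per line with keys `pmid`, `title`, `abstract`,
#' `mesh_headings`, `keywords`, `chemicals`. `write_corpus_jsonl()` followed
#' by `read_corpus_jsonl()` is the identity on corpus content.
#'
#' @param path file path.
#' @param source_label label stored on the returned corpus.
#' @return `read_corpus_jsonl()`: a `corpus`; `write_corpus_jsonl()`: `path`,
#'   invisibly.
#' @export
read_corpus_jsonl <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
    if (is.null(obj$pmid) || !nzchar(as.character(obj$pmid)[1L])) {
      stop("missing pmid on line ", i)
    }
    records[[i]] <- medline_record(
      pmid = obj$pmid,
      title = if (is.null(obj$title)) "" else obj$title,
      abstract = if (is.null(obj$abstract)) "" else obj$abstract,
      mesh_headings = if (is.null(obj$mesh_headings)) character(0) else unlist(obj$mesh_headings),
      keywords = if (is.null(obj$keywords)) character(0) else unlist(obj$keywords),
      chemicals = if (is.null(obj$chemicals)) character(0) else unlist(obj$chemicals)
    )
  }
  corpus(records, source_label)
}

#' @rdname read_corpus_jsonl
#' @param x a `corpus`.
#' @export
write_corpus_jsonl <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in x$records) {
    writeLines(jsonlite::toJSON(
      list(pmid = jsonlite::unbox(rec$pmid),
           title = jsonlite::unbox(rec$title),
           abstract = jsonlite::unbox(rec$abstract),
           mesh_headings = rec$mesh_headings,
           keywords = rec$keywords,
           chemicals = rec$chemicals)), con)
  }
  invisible(path)
}
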