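#' Keyword sets and two-stage corpus classification
#'
#' The pipeline emulates how researchers retrieve microbial studies from
#' PubMed: a record is microbial-related if any token of its matchable text
#' matches a microbial keyword, and microbial-metabolism-related if it
#' additionally matches a metabolism keyword. No supervised classifier is
#' involved.
#'
#' @name classify
NULL

#' Construct a keyword set
#'
#' @param name label for the set.
#' @param keywords character vector of lowercase terms without internal
#'   whitespace; duplicates are removed.
#' @param match_mode `"token-prefix"` (default): a token matches if it begins
#'   with the keyword, so "metabolites" matches "metabolite" but
#'   "antimicrobial" does not match "microbial" (the prefix is anchored at
#'   token start). `"exact-token"`: the token must equal the keyword.
#' @return an object of class `keyword_set`.
#' @export
keyword_set <- function(name, keywords, match_mode = c("token-prefix", "exact-token")) {
  match_mode <- match.arg(match_mode)
  keywords <- unique(as.character(keywords))
  if (!length(keywords)) stop("keywords must be non-empty")
  if (any(!nzchar(keywords)) || any(grepl("\\s", keywords)) ||
      any(keywords != tolower(keywords))) {
    stop("keywords must be non-empty, lowercase, and contain no whitespace")
  }
  structure(list(name = as.character(name), keywords = keywords,
                 match_mode = match_mode),
            class = "keyword_set")
}

#' Preset keyword sets for the two classification stages
#'
#' `"microbial"` gives {microbial, microbiome, microbiota, microflora};
#' `"metabolism"` gives {metabolism, metabolite, metabolic, metabolome}.
#'
#' @param stage `"microbial"` or `"metabolism"`.
#' @param match_mode passed to [keyword_set()].
#' @return a `keyword_set`.
#' @export
preset_keywords <- function(stage = c("microbial", "metabolism"),
                            match_mode = "token-prefix") {
  stage <- match.arg(stage)
  kw <- switch(stage,
    microbial  = c("microbial", "microbiome", "microbiota", "microflora"),
    metabolism = c("metabolism", "metabolite", "metabolic", "metabolome"))
  keyword_set(stage, kw, match_mode)
}

#' Does a record match a keyword set?
#'
#' @param record a `medline_record`.
#' @param ks a `keyword_set`.
#' @param fields field subset passed to [record_text()].
#' @return logical scalar.
#' @export
record_matches <- function(record, ks, fields = MEDLINE_FIELDS) {
  stopifnot(inherits(ks, "keyword_set"))
  toks <- tokenize(record_text(record, fields))
  if (!length(toks)) return(FALSE)
  if (ks$match_mode == "exact-token") {
    any(toks %in% ks$keywords)
  } else {
    any(vapply(ks$keywords,
               function(k) any(startsWith(toks, k)),
               logical(1)))
  }
}

#' Classify a corpus by a keyword set
#'
#' Returns the sub-corpus of records matching `ks`; order and PMIDs are
#' preserved. Applying the metabolism preset to the output of the microbial
#' preset yields the two-stage microbial-metabolism subset.
#'
#' @param x a `corpus`.
#' @param ks a `keyword_set`.
#' @param fields field subset used for matching (default: all five).
#' @return a `corpus` (subset of `x`).
#' @export
classify_corpus <- function(x, ks, fields = MEDLINE_FIELDS) {
  stopifnot(inherits(x, "corpus"))
  keep <- vapply(x$records, record_matches, logical(1), ks = ks, fields = fields)
  out <- corpus(unname(x$records[keep]),
                source_label = paste0(x$source_label,
                                      if (nzchar(x$source_label)) " | " else "",
                                      ks$name, "-classified"))
  out
}
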