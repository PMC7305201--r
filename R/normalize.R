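#' Normalize free text for matching
#'
#' The single text normalization used everywhere in the package: lowercase,
#' every run of non-alphanumeric characters (hyphens, punctuation, symbols)
#' replaced by one space, leading/trailing whitespace removed. Both record
#' text and lexicon synonyms pass through this function, so matching is
#' consistent by construction. Letters and digits outside ASCII are preserved
#' (lowercased, not transliterated).
#'
#' @param x character vector.
#' @return character vector of the same length; each element contains only
#'   lowercase word characters separated by single spaces.
#' @examples
#' normalize_text("TMAO; a metabolite.")   # "tmao a metabolite"
#' normalize_text("Trimethylamine N-oxide") # "trimethylamine n oxide"
#' @export
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^\\p{L}\\p{N}]+", " ", x, perl = TRUE)
  trimws(x)
}

# Split normalized text into its tokens; "" gives character(0).
tokenize <- function(x) {
  x <- normalize_text(x)
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1L]]
}
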