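#' Document-frequency signal prioritization
#'
#' Four ranking formulas score a concept from its document frequency in the
#' classified subset (`dfc`) and in the whole corpus (`df`):
#'
#' \deqn{Rank_1 = df_c}
#' \deqn{Rank_2 = df_c / (df - df_c)}
#' \deqn{Rank_3 = df_c / \ln(df - df_c)}
#' \deqn{Rank_4 = df_c^2 / (df - df_c)}
#'
#' A concept enriched in the classified subset relative to background rises
#' under Rank2-Rank4; Rank4 additionally boosts the classified-subset signal
#' quadratically and is the default method downstream. The formulas are
#' undefined when `df == dfc` (a concept seen only in classified documents),
#' so the denominator is floored at 1: `max(df - dfc, 1)` for Rank2/Rank4,
#' and for Rank3 the denominator is `max(ln(df - dfc), 1)` with the
#' convention that `df - dfc <= 1` also gives denominator 1. The floors keep
#' scores finite and monotone; `rank4 == rank1 * rank2` holds exactly under
#' them.
#'
#' @param dfc,df numeric vectors of counts with `0 <= dfc <= df` (recycled).
#' @return numeric vector of non-negative finite scores.
#' @examples
#' rank4(10, 30)  # 100/20 = 5
#' rank3(10, 110) # 10/ln(100)
#' @name ranking
NULL

check_counts <- function(dfc, df) {
  if (any(dfc < 0) || any(df < 0)) stop("counts must be non-negative")
  if (any(dfc > df)) stop("dfc must not exceed df")
}

#' @rdname ranking
#' @export
rank1 <- function(dfc, df) {
  check_counts(dfc, df)
  as.numeric(dfc)
}

#' @rdname ranking
#' @export
rank2 <- function(dfc, df) {
  check_counts(dfc, df)
  dfc / pmax(df - dfc, 1)
}

#' @rdname ranking
#' @export
rank3 <- function(dfc, df) {
  check_counts(dfc, df)
  rest <- df - dfc
  denom <- ifelse(rest <= 1, 1, pmax(log(rest), 1))
  dfc / denom
}

#' @rdname ranking
#' @export
rank4 <- function(dfc, df) {
  check_counts(dfc, df)
  dfc^2 / pmax(df - dfc, 1)
}

RANK_METHODS <- c("rank1", "rank2", "rank3", "rank4")

#' Score and rank a document-frequency table
#'
#' Scores every concept in the table with the chosen formula and returns a
#' deterministic ranked list: score descending, ties broken by `dfc`
#' descending, then preferred name ascending.
#'
#' @param x a `df_table` (see [compute_df()]).
#' @param method one of `"rank1"`, `"rank2"`, `"rank3"`, `"rank4"`.
#' @return a `ranked_list`: data.frame with columns `rank`, `concept_id`,
#'   `preferred_name`, `score`, `dfc`, `df`. Attribute `floored` counts the
#'   concepts for which the denominator floor was applied.
#' @export
score_table <- function(x, method = c("rank4", "rank1", "rank2", "rank3")) {
  stopifnot(inherits(x, "df_table"))
  method <- match.arg(method)
  d <- as.data.frame(x)
  if (nrow(d) == 0L) {
    out <- data.frame(rank = integer(0), concept_id = character(0),
                      preferred_name = character(0), score = numeric(0),
                      dfc = integer(0), df = integer(0))
    return(structure(out, method = method, floored = 0L,
                     class = c("ranked_list", "data.frame")))
  }
  fn <- switch(method, rank1 = rank1, rank2 = rank2, rank3 = rank3, rank4 = rank4)
  score <- fn(d$dfc, d$df)
  floored <- if (method == "rank1") 0L else sum(d$df - d$dfc <= 1L & d$dfc > 0L)
  ord <- order(-score, -d$dfc, d$preferred_name, method = "radix")
  out <- data.frame(rank = seq_len(nrow(d)),
                    concept_id = d$concept_id[ord],
                    preferred_name = d$preferred_name[ord],
                    score = score[ord],
                    dfc = d$dfc[ord],
                    df = d$df[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, method = method, floored = floored,
            class = c("ranked_list", "data.frame"))
}

#' Write / read a ranked list as TSV
#'
#' Columns: `rank  concept_id  preferred_name  score  dfc  df`.
#'
#' @param x a `ranked_list`.
#' @param path file path.
#' @return writer: `path` invisibly; reader: a `ranked_list`.
#' @export
write_ranked <- function(x, path) {
  stopifnot(inherits(x, "ranked_list"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ranked
#' @export
read_ranked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                         colClasses = c("integer", "character", "character",
                                        "numeric", "integer", "integer"),
                         fileEncoding = "UTF-8")
  structure(x, class = c("ranked_list", "data.frame"))
}
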