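#' Gold-standard evaluation of extraction and ranking
#'
#' Extraction quality is measured against a gold-standard list of known
#' microbial metabolite names with precision, recall and F1; ranking quality
#' with precision at fixed depths (top k) and with precision at fixed recall
#' cutoffs along the ranked list (a step-interpolated PR curve). Gold names
#' are joined to lexicon concepts by the shared normalization, so the gold
#' file can use any synonym spelling that normalizes to a preferred name.
#'
#' @name evaluate
NULL

#' Construct a gold standard
#'
#' @param members character vector of metabolite names; normalized and
#'   deduplicated.
#' @param name label.
#' @return object of class `gold_standard`: normalized member set.
#' @export
gold_standard <- function(members, name = "gold") {
  members <- unique(normalize_text(as.character(members)))
  members <- members[nzchar(members)]
  if (!length(members)) stop("gold standard must be non-empty")
  structure(list(name = as.character(name), members = sort(members)),
            class = "gold_standard")
}

#' Read a gold-standard list from a text file
#'
#' One metabolite name per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @param name label (defaults to the file name).
#' @return a `gold_standard`.
#' @export
read_gold <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  gold_standard(lines[nzchar(lines)], name = name)
}

# Gold membership test for a vector of names (normalized on the way in).
in_gold <- function(names, gold) normalize_text(names) %in% gold$members

#' Precision, recall and F1 of an extracted set
#'
#' `tp = |extracted ∩ gold|`, `fp = |extracted \\ gold|`,
#' `fn = |gold \\ extracted|`; precision `tp/(tp+fp)` (0 when nothing is
#' extracted), recall `tp/(tp+fn)`, F1 the harmonic mean (0 when both are 0).
#'
#' @param extracted character vector of names (normalized internally;
#'   duplicates collapse).
#' @param gold a `gold_standard`.
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
prf <- function(extracted, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  ex <- unique(normalize_text(as.character(extracted)))
  ex <- ex[nzchar(ex)]
  tp <- sum(ex %in% gold$members)
  fp <- length(ex) - tp
  fn <- length(gold$members) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  list(precision = precision, recall = recall,
       f1 = f1_of(precision, recall), tp = tp, fp = fp, fn = fn)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall values in \[0, 1\].
#' @return F1; 0 when both inputs are 0.
#' @examples
#' f1_of(0.055, 0.640)  # ~0.101
#' @export
f1_of <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1)) {
    stop("precision and recall must lie in [0, 1]")
  }
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Precision among the top k of a ranked list
#'
#' @param ranked a `ranked_list` (see [score_table()]).
#' @param gold a `gold_standard`.
#' @param k depth, `1 <= k <= nrow(ranked)`.
#' @return fraction of the first `k` concepts whose preferred name is in the
#'   gold standard.
#' @export
precision_at_k <- function(ranked, gold, k) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(gold, "gold_standard"))
  k <- as.integer(k)
  if (k < 1L || k > nrow(ranked)) {
    stop("k must be between 1 and the length of the ranked list (", nrow(ranked), ")")
  }
  mean(in_gold(ranked$preferred_name[seq_len(k)], gold))
}

#' Precision at fixed recall cutoffs along a ranked list
#'
#' For each recall cutoff r, reports precision at the smallest depth k whose
#' recall reaches r (step interpolation, no smoothing). If the ranked list
#' never attains r (gold members missing from the list), the point carries
#' the precision at full depth and is flagged `attained = FALSE`.
#'
#' @param ranked a `ranked_list`.
#' @param gold a `gold_standard`.
#' @param cutoffs increasing recall levels in (0, 1]; default the 11 standard
#'   levels `c(0.05, 0.1, 0.2, ..., 1.0)`.
#' @return data.frame with columns `recall_cutoff`, `precision`, `depth`,
#'   `attained`.
#' @export
pr_curve <- function(ranked, gold, cutoffs = c(0.05, seq(0.1, 1, by = 0.1))) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(gold, "gold_standard"))
  if (any(cutoffs <= 0 | cutoffs > 1) || is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be strictly increasing within (0, 1]")
  }
  hits <- in_gold(ranked$preferred_name, gold)
  n <- length(hits)
  tp_at <- cumsum(hits)
  recall_at <- tp_at / length(gold$members)
  prec_at <- tp_at / seq_len(n)
  out <- data.frame(recall_cutoff = cutoffs, precision = NA_real_,
                    depth = NA_integer_, attained = NA)
  for (j in seq_along(cutoffs)) {
    # tolerance absorbs seq()-style cutoff representation error (0.3 + 4e-17)
    k <- which(recall_at >= cutoffs[j] - 1e-9)
    if (length(k)) {
      k <- k[1L]
      out$precision[j] <- prec_at[k]; out$depth[j] <- k; out$attained[j] <- TRUE
    } else {
      out$precision[j] <- if (n > 0) prec_at[n] else 0
      out$depth[j] <- n; out$attained[j] <- FALSE
    }
  }
  out
}

#' Signed percent change between two values
#'
#' @param old_value baseline, must be > 0.
#' @param new_value new value.
#' @return `100 * (new - old) / old`.
#' @examples
#' percent_change(0.014, 0.049)  # +250
#' @export
percent_change <- function(old_value, new_value) {
  if (any(old_value <= 0)) stop("old_value must be positive")
  100 * (new_value - old_value) / old_value
}

#' Fold enrichment of an improved value over a baseline
#'
#' @param baseline must be > 0.
#' @param improved new value.
#' @return `improved / baseline`.
#' @export
fold_enrichment <- function(baseline, improved) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  improved / baseline
}
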