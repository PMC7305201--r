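---
title: "metabominer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metabominer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabominer)
```

## The problem and the model

Gut bacteria produce metabolites — short-chain fatty acids, amine oxides,
phenolic and indolic compounds — that circulate in the human body and
mediate microbiome–host interactions. Curated databases flag only a small
set of metabolites as microbial in origin, while many more are described
only in the literature. `metabominer` operationalizes a simple, auditable
alternative to supervised text classification: emulate the keyword searches
a reviewer would run, recognize metabolite names with a dictionary, and let
a document-frequency enrichment statistic separate microbial metabolites
from the (much larger) background of host, food, plant, and drug compounds.

The central modeling assumption is **enrichment**: if a metabolite is
mentioned in microbial-metabolism-related records at a much higher rate than
in the corpus at large, it is more likely to be a microbial metabolite. The
pipeline reduces each concept $m$ to two counts — $df_c(m)$, the number of
*classified* documents mentioning it, and $df(m)$, the number of documents
mentioning it anywhere in the corpus — and ranks by

$$Rank_1 = df_c, \qquad
  Rank_2 = \frac{df_c}{df - df_c}, \qquad
  Rank_3 = \frac{df_c}{\ln(df - df_c)}, \qquad
  Rank_4 = \frac{df_c^2}{df - df_c}.$$

$Rank_1$ is raw popularity inside the classified subset; $Rank_2$ is an
odds-like enrichment ratio; $Rank_3$ dampens the penalty for background
occurrence logarithmically; $Rank_4$ multiplies the ratio by the
classified-subset count (it factors exactly as $Rank_1 \times Rank_2$),
boosting concepts that are both frequent in the classified subset *and*
enriched. The quadratic (rather than higher-order) boost keeps the numerator
from overpowering the background penalty. Document frequency — not mention
frequency — is the unit everywhere: a concept counts once per document
however often it is mentioned.

## Numerical choices

* **Denominator floors.** The ratio formulas are undefined when
  $df = df_c$ (a concept seen only in classified documents), which desk-scale
  corpora readily produce. `rank2()` and `rank4()` use
  $\max(df - df_c,\, 1)$; `rank3()` uses denominator 1 whenever
  $df - df_c \le 1$ and $\max(\ln(df - df_c),\, 1)$ otherwise (the
  $\ln$-floor also absorbs $\ln 2 < 1$). The floors keep every score finite,
  non-negative, and monotone (non-decreasing in $df_c$ at fixed $df$;
  non-increasing in $df$ at fixed $df_c > 0$), and preserve the exact
  identity $Rank_4 = Rank_1 \times Rank_2$. `score_table()` records how many
  concepts were floored in the `floored` attribute.
* **Tie-breaking.** Ranked output orders by score descending, then $df_c$
  descending, then preferred name ascending — a total order, so re-ranking
  is bit-identical across platforms.
* **Text normalization.** One shared normalization everywhere (records,
  lexicon synonyms, gold lists, chemical names): lowercase, every
  non-alphanumeric character to a space, whitespace collapsed. Hyphens
  split tokens, so "n-oxide" tokenizes as `n oxide` on both sides of every
  comparison; non-ASCII letters are lowercased, not transliterated.
* **Matching dialect.** Keyword classification is token-*prefix* matching
  anchored at token start: it catches plurals ("metabolites") the way a
  search engine's truncation would, while excluding embeddings like
  "antimicrobial". Exact-token mode is available
  (`keyword_set(..., match_mode = "exact-token")`). Entity recognition is
  token-sequence matching (never raw substring — "catecholamine" cannot fire
  "choline") with leftmost-longest resolution of overlaps, so
  "trimethylamine" does not fire inside "trimethylamine n-oxide", while a
  separate free-standing occurrence elsewhere in the document still counts.
  Ambiguous synonyms contribute all their concepts and are listed in
  `lexicon_stats()` for curation.
* **Lexicon hygiene.** Synonyms that normalize to the empty string, fall
  below the stop-length (2 characters), or are purely numeric are dropped
  with a warning, not an error — real synonym exports contain such noise.
* **PR curve definition.** Precision is reported at the *minimal* depth
  whose recall reaches each cutoff (step interpolation, no smoothing), the
  standard ranked-retrieval convention. A cutoff the list never attains
  (gold members absent from the ranking) is emitted with full-depth
  precision and `attained = FALSE` rather than dropped. Cutoff comparison
  uses a $10^{-9}$ tolerance because `seq(0.1, 1, 0.1)` does not represent
  0.3 exactly.
* **Division conventions.** Precision of an empty extraction is 0 (not
  NaN); F1 is 0 when precision and recall are both 0; `percent_change()`
  and `fold_enrichment()` require a positive baseline.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| classification fields | all five record fields | — | titles alone miss metabolites listed only in MeSH/chemical fields |
| `match_mode` | `token-prefix` | — | emulates search-engine truncation; anchored to avoid "antimicrobial" |
| ranking `method` | `rank4` | — | strongest enrichment signal of the four (see below) |
| `at_k` | 20, 50, 70, 100 | ranks | standard curation depths for a top-100 manual review |
| `pr_cutoffs` | 0.05, 0.1, ..., 1.0 | recall | 11 levels; dense at the top where curation happens |
| lexicon `min_chars` | 2 | characters | single-character synonyms match pathologically |
| chem-gene `min_score` | none | resource units | name-join only; confidence filtering is opt-in because association tables differ in score semantics |

## What the synthetic generator emulates

`generate_bundle()` builds a world in which the enrichment hypothesis is
*true by construction*: `n_planted` concepts occur in classified documents
with probability `p_signal` per document and everywhere else with
`p_background`; all other concepts occur with `p_background` throughout.
Defaults — 2,000 documents, 10% classified, 200 concepts, 20 planted,
`p_signal = 0.3`, `p_background = 0.01` — give planted concepts an expected
$df_c \approx 60$ against an expected background remainder
$df - df_c \approx 18$, a strong but not degenerate signal; 0.01 is a
realistic per-document rate for a moderately common chemical name, and 30%
is the mention rate of a topic central to a specialized subliterature. A
further 5% of documents are microbial-related but not metabolism-related, so
the two classification stages differ and the subset-containment chain is
exercised.

Construction guarantees **exact** self-consistency, which the test suite
relies on: every synonym carries a globally unique base token (multi-word
synonyms append a suffix token never used standalone), and the filler/title
vocabulary is disjoint from synonym tokens and from classification-keyword
prefixes. Therefore recognition over a generated corpus reproduces the truth
manifest's realized $df/df_c$ *exactly*, and keyword classification recovers
the classified subset *exactly* — a green self-consistency test establishes
that the scanner, classifier, and counter agree perfectly with ground truth,
not merely statistically.

What the generator does **not** emulate — and what a green test therefore
does not establish:

* **Heavy-tailed concept frequencies.** Every non-planted concept shares one
  background rate. Real metabolite mentions are Zipf-like: very common terms
  ("hydrogen") and very rare ones coexist. This matters for method
  comparison: $Rank_2$'s real failure mode is rare concepts whose small
  $df - df_c$ (floored at 1) inflates the ratio, and very common concepts
  whose huge background swamps a genuine signal. With a single background
  rate neither failure mode can occur, and our 20-seed benchmark finds
  $Rank_2$ and $Rank_4$ *both* at precision@20 = 1.0 — the homogeneous world
  is too easy to separate the ratio methods, so the expected
  $Rank_4 > Rank_2$ ordering does not emerge at these settings. The
  corresponding strict-ordering assertion in the acceptance suite is left
  failing rather than weakened; demonstrating the ordering would require
  per-concept background heterogeneity, which the generator's configuration
  deliberately does not include.
* **Linguistic realism.** Documents are bags of filler words with embedded
  mentions; there is no syntax, negation, or hedging. Dictionary NER is
  insensitive to these, but nothing here validates behavior on real prose
  beyond tokenization and multi-word matching.
* **Lexicon noise.** Synthetic synonyms are collision-free; real synonym
  exports contain cross-concept ambiguity and near-miss spellings. Ambiguity
  handling is tested with hand-built cases instead.
* **Metadata.** No MeSH hierarchy, no publication dates, no citation
  structure.

## Design choices where the design was open

* **Chemicals field.** Registry numbers carried alongside substance names
  are not indexed; identity is by name only. Resolving identifiers
  (InChI/CAS) is a different problem with different failure modes.
* **Gold and chemical joins are name-based.** Gold lists and chemical–gene
  tables join to lexicon concepts through the shared normalization, plus an
  optional user-supplied alias table for manual equivalences
  (e.g., mapping a preferred name to a resource's different spelling).
  Unmatched names are reported, never silently dropped.
* **Curation acceptance is conjunctive.** `merge_curation()` accepts a
  metabolite only when *both* independent curator columns say "yes" —
  precision-oriented, appropriate when curated output seeds a reference
  list.
* **Configs are JSON**, not YAML: the pipeline already depends on `jsonlite`
  and nothing else.
* **Floors are logged, not hidden.** Whenever a ranking denominator is
  floored the count is attached to the ranked list, since floored scores are
  an artifact convention, not part of the enrichment model.

## Known limitations

* Dictionary NER cannot find metabolites absent from the lexicon; de-novo
  recognition (pattern learning) is out of scope.
* Token-prefix classification inherits keyword-search recall limits: a
  record discussing a microbial metabolite without any classification
  keyword is invisible to stage 1 (expanding the keyword sets, e.g. with
  bacterial species names, is supported via `keyword_set()`).
* Enrichment ranking underperforms on concepts common in both classified
  and background literature, where $df - df_c$ is large for reasons
  unrelated to microbial origin.
* The gene score is a count of name-joined associations; it inherits every
  bias of the association table and is not a statistical test.
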