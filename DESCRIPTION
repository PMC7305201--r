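Package: metabominer
Title: Mining and Prioritizing Microbial Metabolites from Biomedical Literature
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated text-mining pipeline for discovering gut microbial
    metabolites in bibliographic records. Reads MEDLINE-format tagged exports,
    classifies records into microbial- and microbial-metabolism-related subsets
    with keyword search emulation, performs dictionary-based named entity
    recognition against a metabolite synonym lexicon with leftmost-longest
    matching, prioritizes extracted concepts with four document-frequency
    ranking formulas, evaluates ranked output against gold-standard metabolite
    lists (precision/recall/F1, precision at k, precision-recall curves at
    fixed recall cutoffs), and scores human genes by the number of associated
    prioritized metabolites. Includes a seeded synthetic-corpus generator with
    planted enrichment so the full pipeline is testable without external
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
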