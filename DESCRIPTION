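Package: clinlang
Title: Quantitative Language Measures for Clinical Text Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying written language in clinical and research
    settings: classic readability indices (Flesch Reading Ease, Flesch-Kincaid,
    Gunning Fog, Coleman-Liau, Automated Readability Index, SMOG, Linsear
    Write, Dale-Chall, passive-sentence percentage, difficult-word counts),
    lexical diversity measures (TTR, CTTR, Maas, MSTTR, Herdan's C) and
    propositional idea density from dependency annotations, grapheme-to-phoneme
    conversion with phoneme distributions, part-of-speech, constituent and
    named-entity distributions, heuristic grammar-error flags (fragments,
    run-ons, neologisms), and Damerau-Levenshtein spelling and phonology
    scoring with per-error-type decomposition for target/response word lists.
    Includes a deterministic rule-based annotation backend and a synthetic
    fixture generator with exact ground-truth counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readxl,
    stats,
    tools,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
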