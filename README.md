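# clinlang

Quantitative language measures for clinical text assessment in R.

Speech-language pathologists, neurologists, and researchers studying
conditions that affect language — primary progressive aphasia, post-stroke
aphasia, mild cognitive impairment, developmental language disorder — rely on
quantitative measures of connected speech and writing: how readable a text
is, how lexically diverse, how densely it packs ideas, how its
part-of-speech and entity distributions deviate from healthy controls, and
how far a patient's spelled or spoken production falls from its target.
`clinlang` computes this measure battery from plain text, deterministically
and offline, so scores are reproducible across patients, sessions, and
studies.

## What it computes

**Readability** (per document, from counts of words *w*, sentences *s*,
syllables *y*, letters *l*, characters *c*, complex words *cx*, difficult
words *dw*):

- Flesch Reading Ease `206.835 − 1.015 (w/s) − 84.6 (y/w)`, reported capped
  at 100, with school-level interpretation bands
- Flesch-Kincaid grade `0.39 (w/s) + 11.8 (y/w) − 15.59`
- Gunning Fog `0.4 [(w/s) + 100 (cx/w)]` (complex = 3+ syllables)
- Coleman-Liau `0.0588 L − 0.296 S − 15.8` with L, S per 100 words
- Automated Readability Index `4.71 (c/w) + 0.5 (w/s)` (a conventional
  `−21.43` variant is available)
- SMOG `1.0430 √(polysyllables × 30/s) + 3.1291`, with ten-sentence
  sampling from the beginning, middle and end of long texts
- Linsear Write on the first 100-word sample
- Passive-sentence percentage (via passive-auxiliary / passive-subject
  dependency labels)
- Dale-Chall `0.1579 (100 dw/w) + 0.0496 (w/s)`, `+3.6365` when difficult
  words exceed 5%, against a configurable easy-word list
- Difficult-word count

**Lexical**: character density, mean sentence length, the function/content
word partition used in agrammatism research, propositional idea density
(unique subject/object/clausal dependency propositions per word), and the
TTR family — TTR, CTTR, Maas, MSTTR, Herdan's C.

**Phonology**: grapheme-to-phoneme conversion to IPA through a pluggable
backend (a deterministic rule engine with contextual rules — e.g. final *-s*
voices to /z/ after voiced segments — ships with the package), syllable
counts, and phoneme count/proportion distributions.

**Morphosyntax & semantics**: POS distributions, constituent counts (noun /
verb / prepositional phrases from dependency subtrees), named-entity
distributions, and a per-token word-labeling table (word, syllables, lemma,
POS, POS detail, dependency).

**Grammar flags**: heuristic fragments, run-ons, heavy subordination, and
dictionary-based nonword detection split into phonemic-paraphasia candidates
(within edit distance 2 of a dictionary word) and neologisms, with hapax
marking.

**Clinical scoring**: restricted Damerau-Levenshtein edit scripts (unit-cost
insertions, deletions, substitutions, adjacent transpositions) over letters
(word mode) or IPA segments (non-word and phonology modes), with composite
similarity `1 − distance / max(length)` and a per-error-type decomposition
that always sums to the distance; batch scoring over CSV/TSV/XLSX
target–response tables.

All annotation flows through a pluggable backend; the bundled `rule_en`
backend (lexicon + suffix heuristics + rule-based dependency pass) is fully
deterministic and needs no model downloads.

## Worked example

```r
library(clinlang)
txt <- paste(
  "The ball was thrown by John.",
  "My friend's house is always decorated beautifully.",
  "The dog sleeps in the bedroom.")
doc <- annotate(txt)
readability(doc)
#> Readability report
#>   words 20, sentences 3, syllables 28
#>   flesch_reading_ease          81.628
#>   flesch_kincaid_grade         3.53
#>   gunning_fog                  6.667
#>   coleman_liau                 5.632
#>   automated_readability_index  24.057
#>   smog                         7.794
#>   linsear_write                20
#>   passive_percent              66.667
#>   dale_chall_adjusted          6.336
#>   difficult_words              3
#>   Flesch level: 6th grade / Easy to read
#>   Coleman-Liau level: 5th grade and below / Very easy
```

A Flesch score of 81.6 puts the text in the "easy to read" band; 66.7%
passive reflects that two of the three sentences are passive clauses. The
lexical report on the same document gives `pid = 0.25` (5 unique
propositions over 20 words) and `ttr = 90` (18 types over 20 tokens).

Phonological scoring of a target/response pair:

```r
phonology_score("cat", "tack")
#>   target response    mode distance similarity insertions deletions
#> 1    cat     tack phoneme        2  0.3333333          0         0
#>   substitutions transpositions status
#> 1             2              0     ok
```

/kæt/ versus /tæk/ differ in two non-adjacent substitutions (k↔t), not a
transposition, so the composite phonemic similarity is 1 − 2/3.

A thin CLI over these functions is installed at
`system.file("cli", "clinlang", package = "clinlang")`.

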