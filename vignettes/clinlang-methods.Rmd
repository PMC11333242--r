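---
title: "Methods: how clinlang measures language"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how clinlang measures language}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinlang)
```

## The pipeline and its assumptions

Every measure in the package consumes one container, the
`annotated_document`: a token table with sentence spans, syllabification,
lemma, universal POS, fine-grained tag, dependency relation with head index,
and entity label. The pipeline is `raw_text() -> tokenize() ->
segment_sentences() -> annotate()`, and the annotation step is a pluggable
backend so that an industrial statistical parser can be swapped in without
touching any metric code.

The backend that ships with the package, `rule_en`, is a deterministic
rule-based annotator for English: a closed lexicon for function words,
auxiliaries, and common content words; suffix heuristics (-ly, -ed, -ing,
-tion, ...) with two contextual repairs (a base-form verb after a determiner
is re-read as a noun; an s-form is re-read as a 3rd-singular verb in an
otherwise verbless clause); and a rule-based dependency pass that assigns
one root per sentence, subjects, objects, prepositional attachment,
possessives, and — importantly for the passive-percentage measure — passive
auxiliaries and passive subjects (a form of *be* followed by a past
participle). Entity labels come from a small gazetteer plus a
capitalization rule, with numerals mapped to Quantity.

The consequence to keep in mind: determinism and reproducibility are exact,
but linguistic coverage is that of a rule system, not a trained parser. On
the simple declarative register the test corpus and fixture generator use,
the labels are reliable; on free clinical discourse a statistical backend
should be registered via `register_annotation_backend()`. The `precision`
flag exists for backends that offer a larger model; it is recorded but by
design never alters any formula, and with the single-model rule backend it
does not alter output at all.

**Tokenization conventions** (these define "word count" for every formula):
a word token contains at least one letter or digit; punctuation tokens are
never counted. Possessive and contracted clitics (`'s`, `n't`, ...) are
separate word tokens, and hyphenated compounds remain single tokens. The
same conventions feed the letter counts (letters only, for Coleman-Liau)
and character counts (letters + digits, for ARI).

## Syllabification

Readability formulas need stable counts, not phonologically perfect splits.
The syllabifier is orthographic: maximal vowel groups form nuclei (with *y*
consonantal word-initially or before a vowel, and *u* inert after *q*),
silent final *e* is merged into the previous syllable (except *-le* after a
consonant), final *-ed* is syllabic only after *t*/*d*, final *-es* only
after sibilants, and a small exception table covers common hiatus words
(*science*, *piano*, *create*, ...). Joining the returned syllables always
reproduces the lowercased word, the function is total over strings with at
least one letter, and its output is context-free — the same word never
changes count with its surroundings.

## Readability choices

* **Flesch Reading Ease** is the only capped score (reported 100 when the
  raw value exceeds 100); raw and capped values are both returned.
  Flesch-Kincaid, Coleman-Liau, and ARI are left unclamped — simple texts
  legitimately produce negative grades.
* **ARI** defaults to the formula without the conventional −21.43 constant,
  because that is the form the report surfaces; the conventional variant is
  one argument away (`variant = "conventional"`). Note the as-printed form
  cannot produce the kindergarten anchor score of 1, which is why the
  variant exists.
* **SMOG** prescribes three ten-sentence samples without fixing placement;
  we take them from the beginning, middle, and end of texts with at least
  30 sentences, and use all sentences otherwise (the `30/sentences` factor
  already normalizes short texts).
* **Linsear Write** uses the first 100 word tokens; shorter texts use all
  words with points scaled to a 100-word basis. The branch boundary is
  inclusive: `r = 20` takes the `r/2 − 1` branch.
* **Dale-Chall** counts difficult words per occurrence, case-folded. The
  bundled easy-word list (`inst/extdata/easy_words_en.txt`, ~1060 words) is
  a synthetic common-English list assembled for this package — it is *not*
  the published 3000-word list, which is distributed separately — and every
  function that uses it accepts a replacement vector or file path. The
  +3.6365 adjustment applies strictly above the 5% difficult-word share;
  5% exactly is unadjusted.
* **Passive percentage** counts a sentence once if it contains either a
  passive auxiliary or a passive nominal subject label.

## Lexical choices

* **Characters** are the non-whitespace characters of word tokens;
  punctuation does not inflate density.
* **Propositions** are tokens whose dependency relation falls in {nominal
  subject (active and passive), direct object, adjectival clause, adverbial
  clause, open and closed clausal complement, relative clause, object of a
  preposition}, identified by (relation, head lemma, dependent lemma) and
  deduplicated. The object-of-preposition relation is included so that a
  locative predicate ("the cat was **on the mat**") carries a proposition,
  matching the classic two-proposition reading of "The cat sat on the mat".
* **PID** is unique propositions per *word*. The per-sentence reading that
  sometimes appears alongside this definition is intentionally not
  implemented: the worked reference point (100 propositions / 1000 words =
  0.1) fixes the per-word convention.
* **Types** for the diversity family are case-folded surface forms by
  default (`types = "lemma"` switches to lemmas). Logarithms are natural.
  MSTTR uses 100-token segments, dropping the incomplete final segment.
* **Maas** defaults to `ln(ln V)/ln(ln N)` — the form this toolkit reports —
  with the canonical `a² = (ln N − ln V)/ln²N` behind
  `maas_variant = "a2"`. The default is undefined (NA) when V or N ≤ e.

## Phonology choices

The bundled G2P backend is a rule engine, not a lookup of a pronunciation
dictionary: multigraph rules (digraphs, vowel teams, *-tion*), silent-e
vowel lengthening, soft *c*/*g*, and a contextual inflectional rule — final
*-s* surfaces as /ɪz/ after sibilants, /z/ after voiced segments, /s/
otherwise — plus a ~70-word exception lexicon for common irregular words.
Segments are emitted as units (diphthongs and affricates are one phoneme
each), never re-split into Unicode code points, and no stress marks are
produced, so phoneme distributions count segmental material only. The same
backend drives the non-word spelling mode and phonology scoring, which is
what makes homophonic spellings of a non-word (e.g. *dake* / *daik*) score
a distance of zero.

## Constituents, entities, grammar flags

Phrase counts are derived from dependency subtrees, since no constituency
grammar is involved anywhere in the pipeline: an NP is a maximal
nominal-headed subtree (a nominal attached to another nominal by a
phrase-internal relation such as possessor or compound is not maximal), a
PP is an adposition-headed subtree, and a VP is a non-auxiliary verbal
head. Entity mentions merge adjacent same-label tokens and count per
occurrence.

The grammar flags are deliberately coarse screening heuristics, with the
thresholds exposed as arguments: a fragment lacks a finite root clause with
a subject–predicate pair; a run-on has two or more independently-subjected
finite clauses with no coordinator, subordinator, or internal punctuation;
a complex sentence has ≥ 3 subordinate clauses (no published numeric
definition exists, so this default is a design choice). Nonwords are
dictionary misses; those within restricted Damerau-Levenshtein distance 2
of a dictionary word are labelled phonemic-paraphasia candidates, the rest
neologisms, and document-unique ones are additionally marked hapax. The
bundled dictionary is the easy-word list plus mechanically generated
regular inflections — permissive by construction; supplying a full
dictionary tightens the screen.

## Edit scripts and scoring

"Levenshtein distance with transpositions" is implemented as restricted
Damerau-Levenshtein (optimal string alignment): unit-cost insertions,
deletions, substitutions, and adjacent transpositions, with each substring
edited at most once. The restriction keeps the error-type decomposition
well defined, which is the clinical point of the scorer. Because many
minimal scripts can exist, the backtrace breaks ties deterministically —
match > substitution > transposition > deletion > insertion, scanning from
the sequence ends — so per-type counts are reproducible run to run; the
test suite checks the reported decomposition against the full set of
minimal decompositions enumerated by an independent brute-force program.
Clinical scoring sheets that report "inversions" will find that count in
the substitutions column; the composite score is the standard normalized
similarity `1 − d / max(|target|, |response|)`, in [0, 1], computed over
letters in word mode and phoneme segments otherwise. Word-mode comparison
is case-folded and accent-preserving.

## The fixture generator

`generate_fixture()` emulates the structural skeleton clinical elicitation
texts share — short transitive clauses, a controllable share of passive
clauses, adjectival padding to a target sentence length, and a controllable
share of out-of-dictionary nonce words — from a closed vocabulary whose
syllable counts are fixed by construction and verified once against the
syllabifier. Because the truth values (words, sentences, syllables,
passives, difficult words, types) are computed while the text is built,
metric tests compare pipeline output against construction-time ground
truth rather than against the pipeline itself. Draws come from an internal
linear congruential generator seeded by `seed`, so generation is
byte-identical across runs and does not touch R's global RNG state.

What the generator does *not* emulate: disfluencies, fragments,
morphological errors, topic drift, or any property of real patient
discourse beyond surface structure. Passing tests demonstrate that the
measures compute their definitions correctly, not that the rule backend
parses impaired speech accurately.

## Numerical and scale choices

Scores are double precision throughout; the Dale-Chall adjustment and
similar constants are applied as exact literals, and oracle comparisons in
the suite run at 1e-9. Degenerate inputs are handled by contract: empty or
whitespace-only text raises a typed `cl_empty_input` condition everywhere,
Maas and MSTTR return NA markers when undefined, and empty edit-script
comparisons have distance 0 and similarity 1. Problem sizes in the test
suite — the exhaustive edit-distance grid over all string pairs up to
length 4 on a three-letter alphabet plus a fixed sample of length-5 pairs
(~16,000 pairs), 50-tuple formula oracles, and fixture texts of up to ~100
words — were chosen as the smallest sizes that exercise every branch and
boundary of the algorithms.

## Known limitations

* The rule backend's dependency analysis covers simple declarative and
  passive clauses well; coordination chains, long-distance dependencies,
  and questions receive approximate attachments.
* Clitic tokens (`'s`) count as word tokens, so they appear in word counts
  and — being absent from wordlists — in difficult-word counts.
* The bundled G2P targets English; other supported languages require
  registering a backend (`register_g2p_backend()`).
* XLSX files are read (pair tables) but reports are written as CSV/TSV/JSON.
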