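# Readability indices. Each index is exposed both as a pure count-based
# formula (so counts can come from anywhere and the arithmetic can be checked
# in isolation) and through readability(), which derives the counts from an
# annotated document and assembles the full report.

.check_counts <- function(words, sentences) {
  if (!is.finite(words) || !is.finite(sentences) || words < 1 || sentences < 1) {
    cl_empty_input("count input (need >= 1 word and >= 1 sentence)")
  }
}

#' Flesch Reading Ease
#'
#' `206.835 - 1.015 (words/sentences) - 84.6 (syllables/words)`. Scores above
#' 100 arise for maximally simple texts; the reported score is capped at 100
#' by convention, and both raw and capped values are returned.
#'
#' @param words,sentences,syllables non-negative counts (words, sentences >= 1).
#' @return list with `raw` and `score` (capped at 100).
#' @export
flesch_reading_ease <- function(words, sentences, syllables) {
  .check_counts(words, sentences)
  raw <- 206.835 - 1.015 * (words / sentences) - 84.6 * (syllables / words)
  list(raw = raw, score = min(raw, 100))
}

#' Flesch-Kincaid grade level
#'
#' `0.39 (words/sentences) + 11.8 (syllables/words) - 15.59`; unbounded (very
#' simple texts go below 0, no clamping is applied).
#' @inheritParams flesch_reading_ease
#' @return numeric grade level.
#' @export
flesch_kincaid_grade <- function(words, sentences, syllables) {
  .check_counts(words, sentences)
  0.39 * (words / sentences) + 11.8 * (syllables / words) - 15.59
}

#' Gunning Fog index
#'
#' `0.4 [ words/sentences + 100 complex/words ]`, where complex words have
#' three or more syllables.
#' @inheritParams flesch_reading_ease
#' @param complex_words count of words with >= 3 syllables.
#' @return numeric score.
#' @export
gunning_fog <- function(words, sentences, complex_words) {
  .check_counts(words, sentences)
  0.4 * ((words / sentences) + 100 * (complex_words / words))
}

#' Coleman-Liau index
#'
#' `0.0588 L - 0.296 S - 15.8` with `L` = letters per 100 words and `S` =
#' sentences per 100 words. Letters only (digits excluded).
#' @inheritParams flesch_reading_ease
#' @param letters letter count.
#' @return numeric score.
#' @export
coleman_liau <- function(words, sentences, letters) {
  .check_counts(words, sentences)
  L <- letters / words * 100
  S <- sentences / words * 100
  0.0588 * L - 0.296 * S - 15.8
}

#' Automated Readability Index
#'
#' Default is `4.71 (characters/words) + 0.5 (words/sentences)` (characters =
#' letters + digits). `variant = "conventional"` adds the widely used
#' `-21.43` constant instead.
#' @inheritParams flesch_reading_ease
#' @param characters letter + digit count.
#' @param variant `"as_printed"` (default) or `"conventional"`.
#' @return numeric score.
#' @export
automated_readability_index <- function(words, sentences, characters,
                                        variant = c("as_printed", "conventional")) {
  .check_counts(words, sentences)
  variant <- match.arg(variant)
  base <- 4.71 * (characters / words) + 0.5 * (words / sentences)
  if (variant == "conventional") base - 21.43 else base
}

#' SMOG index
#'
#' `1.0430 sqrt(polysyllables * 30 / sentences) + 3.1291`. The counts should
#' come from three ten-sentence samples when the text is long enough;
#' [readability()] samples ten sentences from the beginning, middle, and end
#' for texts of 30+ sentences, and uses the whole text otherwise (the
#' 30/sentences factor normalizes short texts).
#' @inheritParams flesch_reading_ease
#' @param polysyllables count of words with >= 3 syllables in the sample.
#' @return numeric score (>= 3.1291).
#' @export
smog <- function(sentences, polysyllables) {
  if (!is.finite(sentences) || sentences < 1) {
    cl_empty_input("count input (need >= 1 sentence)")
  }
  1.0430 * sqrt(polysyllables * 30 / sentences) + 3.1291
}

# sentence indices used for the SMOG sample
.smog_sample <- function(n_sentences) {
  if (n_sentences < 30L) return(seq_len(n_sentences))
  mid <- (n_sentences - 10L) %/% 2L + 1L
  c(1:10, seq(mid, mid + 9L), seq(n_sentences - 9L, n_sentences))
}

#' Linsear Write formula
#'
#' Scores the first 100 word tokens: 1 point per word of one or two
#' syllables, 3 points per word of three or more; divide points by the number
#' of sentences in the sample to get `r`; the result is `r/2` if `r > 20`,
#' else `r/2 - 1`. For texts under 100 words all words are used and points are
#' scaled to a 100-word basis.
#'
#' @param doc an annotated document (or text, annotated on the fly).
#' @return numeric grade level.
#' @export
linsear_write <- function(doc) {
  doc <- as_document(doc)
  w <- word_tokens(doc)
  if (nrow(w) == 0L) cl_empty_input()
  take <- utils::head(seq_len(nrow(w)), 100L)
  sample_w <- w[take, , drop = FALSE]
  points <- sum(ifelse(sample_w$n_syllables >= 3L, 3, 1))
  if (nrow(w) < 100L) points <- points * 100 / nrow(w)
  n_sent <- length(unique(sample_w$sentence))
  r <- points / n_sent
  if (r > 20) r / 2 else r / 2 - 1
}

#' Percentage of passive sentences
#'
#' A sentence counts as passive when it contains a passive auxiliary or
#' passive nominal subject dependency relation.
#' @param doc an annotated document (or text).
#' @return percentage in `[0, 100]`.
#' @export
passive_percent <- function(doc) {
  doc <- as_document(doc)
  toks <- doc$tokens
  passive_sent <- unique(toks$sentence[toks$dep %in% c("auxpass", "nsubjpass")])
  100 * length(passive_sent) / nrow(doc$sentences)
}

#' Dale-Chall readability score
#'
#' `0.1579 (100 difficult/words) + 0.0496 (words/sentences)`; when the share
#' of difficult words exceeds 5%, 3.6365 is added to obtain the adjusted
#' score, otherwise adjusted equals raw. Difficult words are word tokens
#' (case-folded, counted per occurrence) absent from the easy-word list.
#'
#' @inheritParams flesch_reading_ease
#' @param difficult_words count of words outside the easy list.
#' @return list with `raw` and `adjusted`.
#' @export
dale_chall <- function(words, sentences, difficult_words) {
  .check_counts(words, sentences)
  pct_difficult <- difficult_words / words * 100
  raw <- 0.1579 * pct_difficult + 0.0496 * (words / sentences)
  adjusted <- if (pct_difficult > 5) raw + 3.6365 else raw
  list(raw = raw, adjusted = adjusted)
}

#' Count difficult words
#'
#' Word tokens (case-folded) absent from the easy-word list, counted per
#' occurrence.
#' @param doc an annotated document (or text).
#' @param easy_words character vector of easy words, or a path readable by
#'   [read_wordlist()]; `NULL` loads the bundled list.
#' @return integer count.
#' @export
difficult_words <- function(doc, easy_words = NULL) {
  doc <- as_document(doc)
  easy <- as_wordlist(easy_words, default = "easy_words_en.txt")
  sum(!word_tokens(doc, lower = TRUE) %in% easy)
}

.flesch_bands <- data.frame(
  lo = c(90, 80, 70, 60, 50, 30, 10, -Inf),
  label = c(
    "5th grade / Very easy to read",
    "6th grade / Easy to read",
    "7th grade / Fairly easy to read",
    "8th and 9th grade / Standard Plain English",
    "10th to 12th grade / Fairly difficult to read",
    "College Level / Difficult to read",
    "College Graduate / Difficult for the general population",
    "Professional / Exceptionally difficult to read"
  )
)

.coleman_bands <- data.frame(
  lo = c(17, 13, 11, 8, 7, 6, -Inf),
  label = c(
    "Professional / Very hard",
    "College / Difficult",
    "11th and 12th grade / Relatively hard",
    "8th to 10th grade / Conversational English",
    "7th grade / Quite easy",
    "6th grade / Easy to read",
    "5th grade and below / Very easy"
  )
)

#' Grade-level interpretation of a readability score
#'
#' Maps a Flesch Reading Ease or Coleman-Liau score to its published
#' school-level band; a value on a band boundary belongs to the upper band.
#'
#' @param measure `"flesch"` or `"coleman_liau"`.
#' @param score numeric score.
#' @return interpretation string.
#' @export
grade_label <- function(measure, score) {
  bands <- switch(measure,
    flesch = .flesch_bands,
    coleman_liau = .coleman_bands,
    cl_abort(sprintf("no published grade table for measure '%s'", measure),
      "cl_unsupported_measure")
  )
  bands$label[match(TRUE, score >= bands$lo)]
}

#' Readability counts of a document
#'
#' The intermediate counts all readability formulas consume.
#' @param doc an annotated document (or text).
#' @inheritParams difficult_words
#' @return list of counts: `word_count`, `sentence_count`, `syllable_count`,
#'   `letter_count`, `character_count` (letters + digits),
#'   `complex_word_count` / `polysyllable_count` (words with >= 3 syllables),
#'   `difficult_word_count`, `passive_sentence_count`.
#' @export
readability_counts <- function(doc, easy_words = NULL) {
  doc <- as_document(doc)
  w <- word_tokens(doc)
  if (nrow(w) == 0L) cl_empty_input()
  toks <- doc$tokens
  passive_sent <- unique(toks$sentence[toks$dep %in% c("auxpass", "nsubjpass")])
  list(
    word_count = nrow(w),
    sentence_count = nrow(doc$sentences),
    syllable_count = sum(w$n_syllables),
    letter_count = sum(w$letter_count),
    character_count = sum(nchar(gsub("[^\\p{L}0-9]", "", w$surface, perl = TRUE))),
    complex_word_count = sum(w$n_syllables >= 3L),
    polysyllable_count = sum(w$n_syllables >= 3L),
    difficult_word_count = difficult_words(doc, easy_words),
    passive_sentence_count = length(passive_sent)
  )
}

#' Full readability report
#'
#' Computes all ten readability measures of the toolkit for one document:
#' Flesch Reading Ease (raw and capped), Flesch-Kincaid grade, Gunning Fog,
#' Coleman-Liau, Automated Readability Index, SMOG (with ten-sentence
#' sampling for long texts), Linsear Write, passive-sentence percentage,
#' Dale-Chall (raw and adjusted) and the difficult-word count, plus grade
#' interpretations where a published table exists.
#'
#' @param doc an annotated document, `raw_text`, or character scalar.
#' @inheritParams difficult_words
#' @param ari_variant passed to [automated_readability_index()].
#' @return An object of class `readability_report` (a list of scores, the
#'   underlying `counts`, and `level_labels`).
#' @export
readability <- function(doc, easy_words = NULL,
                        ari_variant = c("as_printed", "conventional")) {
  doc <- as_document(doc)
  counts <- readability_counts(doc, easy_words)
  fre <- flesch_reading_ease(counts$word_count, counts$sentence_count,
    counts$syllable_count)
  smog_sents <- .smog_sample(counts$sentence_count)
  w <- word_tokens(doc)
  smog_poly <- sum(w$n_syllables[w$sentence %in% smog_sents] >= 3L)
  dc <- dale_chall(counts$word_count, counts$sentence_count,
    counts$difficult_word_count)
  cl <- coleman_liau(counts$word_count, counts$sentence_count,
    counts$letter_count)
  res <- list(
    flesch_reading_ease = fre$score,
    flesch_reading_ease_raw = fre$raw,
    flesch_kincaid_grade = flesch_kincaid_grade(counts$word_count,
      counts$sentence_count, counts$syllable_count),
    gunning_fog = gunning_fog(counts$word_count, counts$sentence_count,
      counts$complex_word_count),
    coleman_liau = cl,
    automated_readability_index = automated_readability_index(
      counts$word_count, counts$sentence_count, counts$character_count,
      match.arg(ari_variant)),
    smog = smog(length(smog_sents), smog_poly),
    linsear_write = linsear_write(doc),
    passive_percent = passive_percent(doc),
    dale_chall_raw = dc$raw,
    dale_chall_adjusted = dc$adjusted,
    difficult_words = counts$difficult_word_count,
    counts = counts,
    level_labels = c(
      flesch = grade_label("flesch", fre$score),
      coleman_liau = grade_label("coleman_liau", cl)
    )
  )
  structure(res, class = "readability_report")
}

#' @export
print.readability_report <- function(x, digits = 3, ...) {
  cat("Readability report\n")
  cat(sprintf("  words %d, sentences %d, syllables %d\n",
    x$counts$word_count, x$counts$sentence_count, x$counts$syllable_count))
  keys <- c("flesch_reading_ease", "flesch_kincaid_grade", "gunning_fog",
    "coleman_liau", "automated_readability_index", "smog", "linsear_write",
    "passive_percent", "dale_chall_adjusted", "difficult_words")
  for (k in keys) {
    cat(sprintf("  %-28s %s\n", k, format(round(x[[k]], digits))))
  }
  cat(sprintf("  Flesch level: %s\n", x$level_labels[["flesch"]]))
  cat(sprintf("  Coleman-Liau level: %s\n", x$level_labels[["coleman_liau"]]))
  invisible(x)
}
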