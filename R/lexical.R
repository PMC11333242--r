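# Lexical measures: surface counts, the function/content partition used in
# agrammatism research, propositional idea density from dependency relations,
# and the type-token-ratio family of diversity indices.

# POS classes counted as function words (adpositions, auxiliaries,
# coordinating conjunctions, determiners, interjections, particles, pronouns,
# subordinating conjunctions); every other word-token POS is a content word.
.function_pos <- c("ADP", "AUX", "CCONJ", "DET", "INTJ", "PART", "PRON", "SCONJ")

# dependency relations that carry one proposition each; "pobj" (object of a
# preposition) is included so that a locative like "the cat was on the mat"
# contributes a proposition, matching the classic two-proposition reading of
# "The cat sat on the mat".
.proposition_deps <- c("nsubj", "nsubjpass", "dobj", "acl", "advcl",
  "xcomp", "ccomp", "relcl", "pobj")

#' Basic lexical counts
#'
#' Characters are the non-whitespace characters of word tokens (punctuation
#' tokens excluded); character density is characters per word and mean
#' sentence length is words per sentence.
#'
#' @param doc an annotated document (or text).
#' @return list: `characters`, `character_density`, `words`, `sentences`,
#'   `mean_sentence_length`.
#' @export
basic_counts <- function(doc) {
  doc <- as_document(doc)
  w <- word_tokens(doc)
  if (nrow(w) == 0L) cl_empty_input()
  chars <- sum(nchar(w$surface))
  list(
    characters = chars,
    character_density = chars / nrow(w),
    words = nrow(w),
    sentences = nrow(doc$sentences),
    mean_sentence_length = nrow(w) / nrow(doc$sentences)
  )
}

#' Function/content word partition
#'
#' Classifies every word token as a function word (adposition, auxiliary,
#' coordinating conjunction, determiner, interjection, particle, pronoun,
#' subordinating conjunction) or a content word (everything else), the
#' partition used to quantify agrammatism and anomia.
#'
#' @param doc an annotated document (or text).
#' @return list: `function_count`, `function_proportion`, `content_count`,
#'   `content_proportion` (proportions of word tokens; they sum to 1).
#' @export
function_content_partition <- function(doc) {
  doc <- as_document(doc)
  w <- word_tokens(doc)
  if (nrow(w) == 0L) cl_empty_input()
  if (is.null(w$pos)) cl_missing_annotation("POS labels")
  fn <- sum(w$pos %in% .function_pos)
  list(
    function_count = fn,
    function_proportion = fn / nrow(w),
    content_count = nrow(w) - fn,
    content_proportion = (nrow(w) - fn) / nrow(w)
  )
}

#' Extract unique propositions
#'
#' A proposition is one token whose dependency relation is in the proposition
#' set (nominal subject, direct object, adjectival/adverbial clause, open and
#' closed clausal complement, relative clause, object of preposition),
#' identified by the triple (relation, head lemma, dependent lemma) and
#' deduplicated.
#'
#' @param doc an annotated document (or text).
#' @return data.frame with columns `relation`, `head_lemma`,
#'   `dependent_lemma`; zero rows for proposition-free text.
#' @export
extract_propositions <- function(doc) {
  doc <- as_document(doc)
  toks <- doc$tokens
  if (is.null(toks$dep)) cl_missing_annotation("dependency labels")
  hit <- which(toks$dep %in% .proposition_deps)
  props <- data.frame(
    relation = toks$dep[hit],
    head_lemma = toks$lemma[toks$head[hit]],
    dependent_lemma = toks$lemma[hit],
    stringsAsFactors = FALSE
  )
  unique(props)
}

#' Propositional idea density
#'
#' Unique propositions divided by the total number of word tokens: a text
#' with 100 unique propositions among 1000 words has a PID of 0.1.
#'
#' @param doc an annotated document (or text).
#' @return numeric density (>= 0).
#' @export
pid <- function(doc) {
  doc <- as_document(doc)
  n_words <- sum(doc$tokens$is_word)
  if (n_words == 0L) cl_empty_input()
  nrow(extract_propositions(doc)) / n_words
}

#' Lexical diversity measures
#'
#' The TTR family over a vector of (case-folded) word tokens:
#' * `ttr` = 100 V/N (types per hundred tokens),
#' * `cttr` = V / sqrt(2N) (corrected TTR),
#' * `maas` = ln(ln V)/ln(ln N) as the platform defines it, or the canonical
#'   Maas a^2 = (ln N - ln V)/ln(N)^2 with `maas_variant = "a2"`,
#' * `msttr` = mean TTR over consecutive complete segments of
#'   `segment_size` tokens (NA when no complete segment exists),
#' * `herdan_c` = ln V / ln N.
#'
#' @param tokens character vector of word tokens (case-fold first for
#'   surface-form types), or a document whose word tokens are used.
#' @param segment_size MSTTR segment length (default 100 tokens).
#' @param maas_variant `"as_printed"` (default) or `"a2"`.
#' @return list with `types`, `tokens`, `ttr`, `cttr`, `maas`, `msttr`,
#'   `herdan_c`. `maas` is NA when V or N <= e (the double logarithm is
#'   undefined); `herdan_c` is NA for N = 1.
#' @export
diversity <- function(tokens, segment_size = 100L,
                      maas_variant = c("as_printed", "a2")) {
  if (inherits(tokens, c("annotated_document", "raw_text"))) {
    tokens <- word_tokens(as_document(tokens), lower = TRUE)
  }
  maas_variant <- match.arg(maas_variant)
  N <- length(tokens)
  if (N == 0L) cl_empty_input("token vector")
  V <- length(unique(tokens))
  e <- exp(1)
  maas <- if (maas_variant == "a2") {
    if (N > 1) (log(N) - log(V)) / log(N)^2 else NA_real_
  } else if (V > e && N > e) {
    log(log(V)) / log(log(N))
  } else {
    NA_real_
  }
  n_seg <- N %/% segment_size
  msttr <- if (n_seg >= 1L) {
    seg_ttr <- vapply(seq_len(n_seg), function(k) {
      seg <- tokens[seq((k - 1L) * segment_size + 1L, k * segment_size)]
      length(unique(seg)) / segment_size
    }, numeric(1))
    mean(seg_ttr)
  } else {
    NA_real_
  }
  list(
    types = V,
    tokens = N,
    ttr = 100 * V / N,
    cttr = V / sqrt(2 * N),
    maas = maas,
    msttr = msttr,
    herdan_c = if (N > 1) log(V) / log(N) else NA_real_
  )
}

#' Full lexical report
#'
#' @param doc an annotated document, `raw_text`, or character scalar.
#' @inheritParams diversity
#' @param types `"surface"` (case-folded surfaces, default) or `"lemma"`:
#'   what counts as a type for the diversity measures.
#' @return An object of class `lexical_report`.
#' @export
lexical_report <- function(doc, segment_size = 100L,
                           types = c("surface", "lemma"),
                           maas_variant = c("as_printed", "a2")) {
  doc <- as_document(doc)
  types <- match.arg(types)
  counts <- basic_counts(doc)
  part <- function_content_partition(doc)
  toks <- if (types == "lemma") {
    word_tokens(doc)$lemma
  } else {
    word_tokens(doc, lower = TRUE)
  }
  div <- diversity(toks, segment_size, maas_variant)
  props <- extract_propositions(doc)
  structure(
    c(counts, part,
      list(unique_propositions = nrow(props), pid = nrow(props) / counts$words),
      div),
    class = "lexical_report"
  )
}

#' @export
print.lexical_report <- function(x, digits = 3, ...) {
  cat("Lexical report\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.numeric(v)) cat(sprintf("  %-22s %s\n", k, format(round(v, digits))))
  }
  invisible(x)
}
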