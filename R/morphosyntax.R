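# Morphological, syntactic and semantic distributions, plus the per-token
# word-labeling table.

.distribution <- function(values, denom = NULL) {
  counts <- table(values)
  nm <- names(counts)
  counts <- stats::setNames(as.integer(counts),
    if (is.null(nm)) character(0) else nm)
  if (is.null(denom)) denom <- sum(counts)
  structure(
    list(counts = counts,
      ratios = if (denom > 0) counts / denom else counts * NA_real_),
    class = "distribution_report"
  )
}

#' @export
print.distribution_report <- function(x, ...) {
  df <- data.frame(count = x$counts, ratio = round(x$ratios, 4))
  print(df)
  invisible(x)
}

#' Part-of-speech distribution
#'
#' Counts of universal POS categories over word tokens, with ratios relative
#' to the word-token count. Categories with zero occurrences are absent.
#'
#' @param doc an annotated document (or text).
#' @param display use human-readable POS names (default) rather than
#'   universal codes.
#' @return A `distribution_report` with `counts` and `ratios`.
#' @export
pos_distribution <- function(doc, display = TRUE) {
  doc <- as_document(doc)
  w <- word_tokens(doc)
  if (is.null(w$pos)) cl_missing_annotation("POS labels")
  vals <- if (display) pos_display(w$pos) else w$pos
  .distribution(vals, denom = nrow(w))
}

# token indices of the dependency subtree rooted at token i (absolute indices)
.subtree <- function(toks, i) {
  members <- i
  repeat {
    more <- which(toks$head %in% members & !seq_len(nrow(toks)) %in% members &
        toks$dep != "root")
    if (!length(more)) break
    members <- c(members, more)
  }
  sort(members)
}

#' Syntactic constituent counts
#'
#' Phrase counts derived from the dependency tree: noun phrases are maximal
#' nominal-headed subtrees (a nominal head whose own head is not part of a
#' nominal phrase above it), prepositional phrases are adposition-headed
#' subtrees, verb phrases are non-auxiliary verbal heads with their
#' dependents. The sentence count is included.
#'
#' @param doc an annotated document (or text).
#' @return A `distribution_report`; counts for `sentences`, `noun_phrases`,
#'   `verb_phrases`, `prepositional_phrases`; ratios relative to the total
#'   phrase count.
#' @export
constituent_counts <- function(doc) {
  doc <- as_document(doc)
  toks <- doc$tokens
  if (is.null(toks$dep)) cl_missing_annotation("dependency labels")
  nominal <- toks$pos %in% c("NOUN", "PROPN", "PRON")
  # maximal nominal heads: nominal tokens not attached to a nominal via a
  # phrase-internal relation
  internal <- c("det", "amod", "poss", "compound", "nummod", "case")
  # a nominal attached to another nominal by a phrase-internal relation
  # (possessor, compound, ...) is not maximal; a pobj under a preposition
  # still heads its own NP
  np_heads <- which(nominal & !(nominal[toks$head] & toks$dep %in% internal))
  vp_heads <- which(toks$pos == "VERB")
  pp_heads <- which(toks$pos == "ADP" & toks$dep == "prep")
  counts <- c(
    sentences = nrow(doc$sentences),
    noun_phrases = length(np_heads),
    verb_phrases = length(vp_heads),
    prepositional_phrases = length(pp_heads)
  )
  structure(
    list(counts = counts, ratios = counts / sum(counts)),
    class = "distribution_report"
  )
}

#' Named-entity distribution
#'
#' Counts of entity mentions per label. Adjacent tokens with the same label
#' form one mention; repeated mentions count per occurrence.
#'
#' @param doc an annotated document (or text).
#' @return A `distribution_report`; empty counts for entity-free text.
#' @export
entity_distribution <- function(doc) {
  doc <- as_document(doc)
  toks <- doc$tokens
  if (is.null(toks$entity)) cl_missing_annotation("entity labels")
  lab <- toks$entity
  # merge adjacent same-label tokens into single mentions
  mention_labels <- character(0)
  prev <- NA_character_
  for (i in seq_along(lab)) {
    if (!is.na(lab[i])) {
      if (is.na(prev) || prev != lab[i]) mention_labels <- c(mention_labels, lab[i])
    }
    prev <- lab[i]
  }
  .distribution(mention_labels)
}

#' Word-labeling table
#'
#' One row per token in document order: the word, its syllabification, lemma,
#' POS category and fine-grained detail, and its dependency relation, all in
#' human-readable form.
#'
#' @param doc an annotated document (or text).
#' @return data.frame with columns `word`, `syllables`, `lemma`, `pos`,
#'   `pos_detail`, `dependency`.
#' @export
word_label_table <- function(doc) {
  doc <- as_document(doc)
  toks <- doc$tokens
  if (is.null(toks$lemma)) cl_missing_annotation("lemmas")
  syll <- vapply(toks$syllables, function(s) {
    if (is.null(s) || length(s) == 0L) "None"
    else paste(sprintf("'%s'", s), collapse = ", ")
  }, character(1))
  data.frame(
    word = toks$surface,
    syllables = syll,
    lemma = toks$lemma,
    pos = pos_display(toks$pos),
    pos_detail = toks$pos_detail,
    dependency = dep_display(toks$dep),
    stringsAsFactors = FALSE
  )
}
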