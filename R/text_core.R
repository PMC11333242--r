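#' Supported document languages
#'
#' ISO 639-1 codes of the languages the toolkit accepts in [raw_text()].
#' Annotation and grapheme-to-phoneme backends declare their own (typically
#' narrower) coverage; the bundled rule-based backends cover English.
#'
#' @export
supported_languages <- c(
  "en", "da", "nl", "fi", "fr", "de", "el", "it",
  "no", "pl", "pt", "ro", "ru", "es", "sv"
)

#' Construct a raw text object
#'
#' Light wrapper pairing a UTF-8 string with its language code. All metric
#' functions accept either a `raw_text`, an [annotate()]d document, or a plain
#' character scalar (assumed English).
#'
#' @param content character scalar; must be non-empty after whitespace
#'   stripping.
#' @param language ISO 639-1 code, one of [supported_languages].
#' @return An object of class `raw_text`.
#' @export
raw_text <- function(content, language = "en") {
  stopifnot(is.character(content), length(content) == 1L)
  if (is.na(content) || !nzchar(trimws(content))) cl_empty_input()
  if (!language %in% supported_languages) cl_unsupported_language(language)
  structure(list(content = content, language = language), class = "raw_text")
}

#' @export
print.raw_text <- function(x, ...) {
  cat(sprintf("<raw_text [%s], %d chars>\n", x$language, nchar(x$content)))
  invisible(x)
}

# Regex for one token. Order matters: words (with internal hyphens), numbers,
# clitic apostrophe forms ('s, 'll, ...), then any single non-space character.
.token_pattern <- paste0(
  "[\\p{L}]+(?:-[\\p{L}]+)*",
  "|[0-9]+(?:[.,][0-9]+)*",
  "|['’](?:s|S|ll|re|ve|m|d|t)\\b",
  "|\\S"
)

#' Tokenize text
#'
#' Splits text into word and punctuation tokens. Possessive and contracted
#' clitics (`'s`, `'ll`, ...) become separate tokens; hyphenated compounds stay
#' whole; every punctuation mark is its own non-word token. Trailing
#' whitespace of each token is preserved so that pasting `surface` and `ws`
#' back together reconstructs the (trimmed) input.
#'
#' @param text a `raw_text` or character scalar.
#' @return A data.frame with columns `surface`, `ws` (the whitespace that
#'   followed the token in the input), `is_word` (contains a letter or digit),
#'   and `letter_count`.
#' @export
tokenize <- function(text) {
  if (is.character(text)) text <- raw_text(text)
  content <- trimws(text$content)
  if (!nzchar(content)) cl_empty_input()
  m <- gregexpr(.token_pattern, content, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (starts[1] == -1L) cl_empty_input()
  surface <- substring(content, starts, starts + lens - 1L)
  ends <- starts + lens - 1L
  ws <- if (length(surface) > 1L) {
    c(substring(content, ends[-length(ends)] + 1L, starts[-1L] - 1L), "")
  } else {
    ""
  }
  data.frame(
    surface = surface,
    ws = ws,
    is_word = grepl("[\\p{L}0-9]", surface, perl = TRUE),
    letter_count = nchar(gsub("[^\\p{L}]", "", surface, perl = TRUE)),
    stringsAsFactors = FALSE
  )
}

# sentence terminators; closing quotes/brackets after one stay in the sentence
.sent_end <- c(".", "!", "?", "…")
.sent_trail <- c("\"", "'", "’", "”", ")", "]")

#' Segment a token sequence into sentences
#'
#' Punctuation-driven boundary detection: a sentence ends at `.`, `!`, `?` or
#' an ellipsis (plus any closing quotes or brackets that follow); tokens after
#' the last terminator form a final, unterminated sentence.
#'
#' @param tokens a token data.frame from [tokenize()] (or an
#'   `annotated_document`, whose token table is used).
#' @return A data.frame with 1-based inclusive columns `start`, `end`; the
#'   spans are disjoint and cover every token.
#' @export
segment_sentences <- function(tokens) {
  if (inherits(tokens, "annotated_document")) tokens <- tokens$tokens
  n <- nrow(tokens)
  if (is.null(n) || n == 0L) cl_empty_input("token sequence")
  is_end <- tokens$surface %in% .sent_end
  # pull trailing closers into the ending sentence
  bounds <- integer(0)
  i <- 1L
  while (i <= n) {
    if (is_end[i]) {
      j <- i
      while (j < n && tokens$surface[j + 1L] %in% .sent_trail) j <- j + 1L
      bounds <- c(bounds, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(bounds) == 0L || bounds[length(bounds)] < n) {
    bounds <- c(bounds, n)
  }
  starts <- c(1L, bounds[-length(bounds)] + 1L)
  data.frame(start = starts, end = bounds)
}

#' Annotate a text
#'
#' Runs the configured annotation backend over a text, producing an
#' `annotated_document`: one row per token carrying lemma, universal POS,
#' fine-grained tag, dependency relation with head index, entity label, and
#' syllabification. This is the container every metric module consumes.
#'
#' @param text a `raw_text` or character scalar.
#' @param precision logical; selects a larger model where a backend offers one.
#'   The bundled rule backend is a single deterministic model, so the flag is
#'   accepted and recorded but does not change its output (and by design never
#'   changes any downstream formula).
#' @param backend backend name (see [annotation_backends()]) or a backend
#'   object.
#' @return An object of class `annotated_document`: list with `tokens` (one
#'   row per token: `surface`, `ws`, `is_word`, `letter_count`, `syllables`
#'   (list column), `n_syllables`, `lemma`, `pos`, `pos_detail`, `dep`,
#'   `head` (1-based absolute token index; the root points to itself),
#'   `entity`, `sentence`), `sentences` (start/end spans), `language`.
#' @export
annotate <- function(text, precision = FALSE, backend = "rule_en") {
  if (is.character(text)) text <- raw_text(text)
  be <- resolve_backend(backend)
  if (!text$language %in% be$languages) cl_unsupported_language(text$language)
  tokens <- tokenize(text)
  sentences <- segment_sentences(tokens)
  tokens$sentence <- rep.int(
    seq_len(nrow(sentences)),
    sentences$end - sentences$start + 1L
  )
  tokens <- be$annotate(tokens, sentences, text$language, precision)
  syl <- vector("list", nrow(tokens))
  nsyl <- integer(nrow(tokens))
  has_letter <- tokens$letter_count > 0L
  syl[has_letter] <- lapply(tokens$surface[has_letter], syllabify,
    language = text$language)
  nsyl[has_letter] <- lengths(syl[has_letter])
  tokens$syllables <- syl
  tokens$n_syllables <- nsyl
  structure(
    list(tokens = tokens, sentences = sentences, language = text$language,
      backend = be$name, precision = isTRUE(precision)),
    class = "annotated_document"
  )
}

#' @export
print.annotated_document <- function(x, n = 10L, ...) {
  cat(sprintf(
    "<annotated_document [%s]: %d tokens (%d words), %d sentences, backend '%s'>\n",
    x$language, nrow(x$tokens), sum(x$tokens$is_word), nrow(x$sentences),
    x$backend
  ))
  show <- utils::head(x$tokens[, c("surface", "lemma", "pos", "dep", "head")], n)
  print(show)
  if (nrow(x$tokens) > n) cat(sprintf("... and %d more tokens\n", nrow(x$tokens) - n))
  invisible(x)
}

#' Reconstruct the text of a document
#' @param doc an `annotated_document` or token table.
#' @return character scalar equal to the trimmed input text.
#' @export
detokenize <- function(doc) {
  tokens <- if (inherits(doc, "annotated_document")) doc$tokens else doc
  paste0(paste0(tokens$surface, tokens$ws), collapse = "")
}

# Coerce any accepted input to an annotated document.
as_document <- function(x, language = "en", ...) {
  if (inherits(x, "annotated_document")) return(x)
  if (inherits(x, "raw_text")) return(annotate(x, ...))
  if (is.character(x) && length(x) == 1L) {
    return(annotate(raw_text(x, language), ...))
  }
  stop("expected an annotated_document, raw_text, or character scalar")
}

# Word tokens of a document, optionally case-folded surfaces.
word_tokens <- function(doc, lower = FALSE) {
  w <- doc$tokens[doc$tokens$is_word, , drop = FALSE]
  if (lower) tolower(w$surface) else w
}
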