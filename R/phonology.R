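# Grapheme-to-phoneme conversion and phoneme distribution measures. G2P is a
# pluggable backend like annotation; the bundled "rule_g2p_en" backend is a
# deterministic English letter-to-sound rule engine with a small exception
# lexicon. It applies contextual rules rather than letter-by-letter mapping:
# the same grapheme can surface as different phonemes in different
# environments (final -s voices to /z/ after voiced segments, silent final e
# lengthens the preceding vowel, c softens before front vowels, ...).

.g2p_registry <- new.env(parent = emptyenv())

#' Register a grapheme-to-phoneme backend
#' @param backend list with `name`, `languages`, and `convert(word, language)`
#'   returning a character vector of IPA segments.
#' @export
register_g2p_backend <- function(backend) {
  stopifnot(is.list(backend), is.character(backend$name),
    is.function(backend$convert))
  assign(backend$name, backend, envir = .g2p_registry)
  invisible(backend$name)
}

#' List registered G2P backends
#' @return character vector of backend names.
#' @export
g2p_backends <- function() ls(.g2p_registry)

resolve_g2p <- function(backend) {
  if (is.list(backend)) return(backend)
  if (!exists(backend, envir = .g2p_registry)) {
    cl_abort(sprintf("G2P backend '%s' is not registered", backend),
      "cl_backend_error")
  }
  get(backend, envir = .g2p_registry)
}

# exception lexicon: word -> space-separated IPA segments
.g2p_exceptions <- c(
  the = "ð ə", a = "ə", an = "ə n", of = "ə v", to = "t ə",
  is = "ɪ z", was = "w ɒ z", are = "ɑː", were = "w ɜː",
  he = "h iː", she = "ʃ iː", we = "w iː", be = "b iː", me = "m iː",
  i = "aɪ", you = "j uː", do = "d uː", who = "h uː", two = "t uː",
  one = "w ʌ n", once = "w ʌ n s", what = "w ɒ t",
  said = "s ɛ d", have = "h æ v", give = "g ɪ v", live = "l ɪ v",
  there = "ð ɛə", their = "ð ɛə", where = "w ɛə", here = "h ɪə",
  they = "ð eɪ", this = "ð ɪ s", that = "ð æ t", these = "ð iː z",
  those = "ð əʊ z", then = "ð ɛ n", them = "ð ɛ m", than = "ð æ n",
  with = "w ɪ ð", mother = "m ʌ ð ə", father = "f ɑː ð ə",
  friend = "f ɹ ɛ n d", house = "h aʊ s", come = "k ʌ m",
  some = "s ʌ m", love = "l ʌ v", done = "d ʌ n", gone = "g ɒ n",
  move = "m uː v", lose = "l uː z", whose = "h uː z",
  eye = "aɪ", eyes = "aɪ z", island = "aɪ l ə n d",
  hour = "aʊə", honest = "ɒ n ɪ s t", heart = "h ɑː t",
  people = "p iː p ə l", water = "w ɔː t ə", many = "m ɛ n ɪ",
  any = "ɛ n ɪ", again = "ə g ɛ n", against = "ə g ɛ n s t",
  says = "s ɛ z", does = "d ʌ z", knows = "n əʊ z", know = "n əʊ",
  word = "w ɜː d", world = "w ɜː l d", work = "w ɜː k",
  converted = "k ə n v ɜː t ɪ d", always = "ɔː l w eɪ z",
  beautifully = "b j uː t ɪ f ə l ɪ", decorated = "d ɛ k ə ɹ eɪ t ɪ d"
)

.voiced_segments <- c("b", "d", "g", "v", "ð", "z", "ʒ", "dʒ", "m", "n",
  "ŋ", "l", "ɹ", "r", "w", "j")
.sibilant_segments <- c("s", "z", "ʃ", "ʒ", "tʃ", "dʒ")

.is_vowel_seg <- function(seg) {
  grepl("[aeiouæɑɒɔəɜɛɪʊʌː]|eɪ|aɪ|ɔɪ|aʊ|əʊ|ɪə|ɛə|ʊə|aʊə", seg)
}

# ordered multigraph rules applied before single letters
.g2p_multi <- list(
  c("tch", "tʃ"), c("igh", "aɪ"), c("dge", "dʒ"), c("tion", "ʃ ə n"),
  c("sion", "ʒ ə n"), c("ough", "ʌ f"),
  c("ch", "tʃ"), c("sh", "ʃ"), c("th", "θ"), c("ph", "f"), c("wh", "w"),
  c("ng", "ŋ"), c("ck", "k"), c("qu", "k w"), c("kn", "n"), c("wr", "ɹ"),
  c("ee", "iː"), c("ea", "iː"), c("oo", "uː"), c("ou", "aʊ"), c("ow", "aʊ"),
  c("ai", "eɪ"), c("ay", "eɪ"), c("oa", "əʊ"), c("oi", "ɔɪ"), c("oy", "ɔɪ"),
  c("au", "ɔː"), c("aw", "ɔː"), c("ar", "ɑː"), c("or", "ɔː"), c("er", "ə"),
  c("ir", "ɜː"), c("ur", "ɜː"), c("ew", "j uː"), c("ie", "aɪ"),
  c("ll", "l"), c("ss", "s"), c("ff", "f"), c("zz", "z"), c("mm", "m"),
  c("nn", "n"), c("pp", "p"), c("tt", "t"), c("bb", "b"), c("dd", "d"),
  c("gg", "g"), c("rr", "ɹ"), c("cc", "k")
)

.g2p_single <- c(
  a = "æ", e = "ɛ", i = "ɪ", o = "ɒ", u = "ʌ", y = "ɪ",
  b = "b", c = "k", d = "d", f = "f", g = "g", h = "h", j = "dʒ",
  k = "k", l = "l", m = "m", n = "n", p = "p", q = "k", r = "ɹ",
  s = "s", t = "t", v = "v", w = "w", x = "k s", z = "z"
)

# long-vowel values triggered by a silent final e (a_e -> /eɪ/ etc.)
.long_vowel <- c(a = "eɪ", e = "iː", i = "aɪ", o = "əʊ", u = "j uː", y = "aɪ")

.rule_g2p_convert <- function(word, language = "en") {
  w <- tolower(gsub("[^a-z']", "", tolower(word)))
  w <- gsub("'", "", w)
  if (!nzchar(w)) return(character(0))
  hit <- unname(.g2p_exceptions[w])
  if (!is.na(hit)) return(strsplit(hit, " ", fixed = TRUE)[[1]])

  # inflectional -s: convert the stem, then voice the suffix by context
  suffix <- NULL
  stem <- w
  if (grepl("[^su]s$", w) && nchar(w) > 2) {
    stem <- sub("s$", "", w)
    suffix <- "s"
  }

  segs <- .rule_g2p_stem(stem)
  if (!is.null(suffix)) {
    last <- segs[length(segs)]
    segs <- c(segs, if (last %in% .sibilant_segments) c("ɪ", "z")
      else if (last %in% .voiced_segments || .is_vowel_seg(last)) "z"
      else "s")
  }
  segs
}

.rule_g2p_stem <- function(w) {
  hit <- unname(.g2p_exceptions[w])
  if (!is.na(hit)) return(strsplit(hit, " ", fixed = TRUE)[[1]])
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # silent final e: vowel-consonant-e (also across an -ed/-es inflection
  # handled by the caller); mark the long vowel position
  long_at <- NA_integer_
  drop_final_e <- FALSE
  if (n >= 3 && chars[n] == "e" &&
      !chars[n - 1L] %in% c("a", "e", "i", "o", "u") &&
      chars[n - 2L] %in% c("a", "e", "i", "o", "u", "y")) {
    long_at <- n - 2L
    drop_final_e <- TRUE
  }
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (i == n && drop_final_e) break
    # long vowel induced by silent e (single consonant between)
    if (!is.na(long_at) && i == long_at) {
      out <- c(out, .long_vowel[[chars[i]]])
      i <- i + 1L
      next
    }
    matched <- FALSE
    for (rule in .g2p_multi) {
      g <- rule[1L]
      if (i + nchar(g) - 1L <= n &&
          substr(w, i, i + nchar(g) - 1L) == g &&
          !(!is.na(long_at) && long_at >= i && long_at < i + nchar(g))) {
        out <- c(out, strsplit(rule[2L], " ", fixed = TRUE)[[1]])
        i <- i + nchar(g)
        matched <- TRUE
        break
      }
    }
    if (matched) next
    ch <- chars[i]
    ph <- if (ch == "c" && i < n && chars[i + 1L] %in% c("e", "i", "y")) "s"
      else if (ch == "g" && i < n && chars[i + 1L] %in% c("e", "i", "y") &&
        !w %in% c("get", "give")) "dʒ"
      else if (ch == "y" && (i == 1L ||
        (i < n && chars[i + 1L] %in% c("a", "e", "i", "o", "u")))) "j"
      else .g2p_single[[ch]]
    out <- c(out, strsplit(ph, " ", fixed = TRUE)[[1]])
    i <- i + 1L
  }
  if (length(out) == 0L) out <- "ə"
  out
}

rule_g2p_en_backend <- list(
  name = "rule_g2p_en",
  languages = "en",
  convert = .rule_g2p_convert
)

#' Grapheme-to-phoneme conversion
#'
#' Converts words to IPA phoneme sequences through the configured G2P
#' backend. Conversion is context-sensitive (e.g. the plural/3rd-singular
#' `-s` surfaces as /z/, /s/ or /ɪz/ depending on the preceding segment) and
#' deterministic for a fixed backend. Multi-character IPA segments
#' (diphthongs, affricates) are single elements; stress marks are not
#' emitted by the bundled backend and are stripped from lexicon entries.
#'
#' @param x a character vector of words, a `raw_text`, or an annotated
#'   document (word tokens are converted).
#' @param language ISO 639-1 code.
#' @param backend G2P backend name or object (see [g2p_backends()]).
#' @return named list of character vectors of IPA segments, one per word.
#' @examples
#' g2p(c("is", "cat"))
#' @export
g2p <- function(x, language = "en", backend = "rule_g2p_en") {
  be <- resolve_g2p(backend)
  if (!language %in% be$languages) cl_unsupported_language(language)
  words <- if (inherits(x, c("annotated_document", "raw_text"))) {
    word_tokens(as_document(x, language), lower = TRUE)
  } else {
    as.character(x)
  }
  out <- lapply(words, be$convert, language = language)
  names(out) <- words
  out
}

#' Transcribe a text to IPA
#'
#' @inheritParams g2p
#' @param sep separator between words.
#' @return character scalar: slash-delimited IPA transcription of the word
#'   tokens.
#' @export
ipa_transcribe <- function(x, language = "en", backend = "rule_g2p_en",
                           sep = " ") {
  if (is.character(x) && length(x) == 1L) x <- raw_text(x, language)
  segs <- g2p(x, language, backend)
  paste0("/", paste(vapply(segs, paste0, character(1), collapse = ""),
    collapse = sep), "/")
}

#' Phonology report
#'
#' Syllable count and syllable-to-word ratio (from the syllabifier) plus
#' phoneme counts and proportions aggregated over the G2P output of all word
#' tokens.
#'
#' @param doc an annotated document, `raw_text`, or character scalar.
#' @inheritParams g2p
#' @return An object of class `phonology_report`: list with `words`,
#'   `syllable_count`, `syllable_word_ratio`, `phoneme_counts` (named integer
#'   vector) and `phoneme_proportions` (sums to 1).
#' @export
phonology_report <- function(doc, language = NULL, backend = "rule_g2p_en") {
  doc <- as_document(doc)
  if (is.null(language)) language <- doc$language
  w <- word_tokens(doc)
  if (nrow(w) == 0L) cl_empty_input()
  segs <- g2p(w$surface, language, backend)
  all_segs <- unlist(segs, use.names = FALSE)
  counts <- table(all_segs)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(
      words = nrow(w),
      syllable_count = sum(w$n_syllables),
      syllable_word_ratio = sum(w$n_syllables) / nrow(w),
      phoneme_counts = counts,
      phoneme_proportions = counts / sum(counts)
    ),
    class = "phonology_report"
  )
}

#' @export
print.phonology_report <- function(x, ...) {
  cat(sprintf(
    "Phonology report: %d words, %d syllables (ratio %.3f), %d phoneme types\n",
    x$words, x$syllable_count, x$syllable_word_ratio,
    length(x$phoneme_counts)))
  top <- sort(x$phoneme_counts, decreasing = TRUE)
  print(utils::head(top, 12L))
  invisible(x)
}
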