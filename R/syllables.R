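# Syllabification: orthographic vowel-group segmentation with silent-e and
# suffix corrections, plus a small exception table for words English orthography
# splits irregularly. Deterministic and context-free: readability formulas only
# need stable counts, and the same word always yields the same split.

.syllable_exceptions <- local({
  x <- c(
    science = "sci-ence", quiet = "qui-et", diet = "di-et",
    create = "cre-ate", idea = "i-de-a", area = "ar-e-a",
    being = "be-ing", going = "go-ing", doing = "do-ing", seeing = "see-ing",
    really = "real-ly", business = "busi-ness", every = "ev-ery",
    evening = "eve-ning", interesting = "in-ter-est-ing",
    poem = "po-em", lion = "li-on", ion = "i-on", riot = "ri-ot",
    chaos = "cha-os", naive = "na-ive", cooperate = "co-op-er-ate",
    curiosity = "cu-ri-os-i-ty", piano = "pi-an-o", violet = "vi-o-let",
    violin = "vi-o-lin", usual = "u-su-al", usually = "u-su-al-ly",
    actual = "ac-tu-al", actually = "ac-tu-al-ly", annual = "an-nu-al",
    casual = "cas-u-al", visual = "vis-u-al", situation = "sit-u-a-tion",
    evaluation = "e-val-u-a-tion", graduate = "grad-u-ate",
    january = "jan-u-ar-y", february = "feb-ru-ar-y",
    ocean = "o-cean", theater = "the-a-ter", theatre = "the-a-tre",
    museum = "mu-se-um", radio = "ra-di-o", video = "vid-e-o",
    audio = "au-di-o", period = "pe-ri-od", serious = "se-ri-ous",
    various = "var-i-ous", previous = "pre-vi-ous", obvious = "ob-vi-ous",
    experience = "ex-pe-ri-ence", society = "so-ci-e-ty",
    quiescent = "qui-es-cent", diagnosis = "di-ag-no-sis",
    patient = "pa-tient", ancient = "an-cient", fluent = "flu-ent",
    influence = "in-flu-ence", immediate = "im-me-di-ate",
    appropriate = "ap-pro-pri-ate", associate = "as-so-ci-ate",
    aphasia = "a-pha-sia", dementia = "de-men-tia"
  )
  strsplit(unname(x), "-", fixed = TRUE) |> stats::setNames(names(x))
})

.vowel_chars <- c("a", "e", "i", "o", "u", "y",
  "à", "á", "â", "ä", "æ", "è", "é",
  "ê", "ë", "ì", "í", "î", "ï", "ò",
  "ó", "ô", "ö", "ø", "ù", "ú", "û",
  "ü", "å")

# logical mask: which letters act as vowel nuclei
.vowel_mask <- function(chars) {
  n <- length(chars)
  v <- chars %in% .vowel_chars
  for (i in seq_len(n)) {
    if (!v[i]) next
    if (chars[i] == "y") {
      # y is a consonant word-initially or immediately before a vowel nucleus
      if (i == 1L || (i < n && chars[i + 1L] %in% .vowel_chars)) v[i] <- FALSE
    } else if (chars[i] == "u" && i > 1L && chars[i - 1L] == "q") {
      v[i] <- FALSE # qu- onset
    }
  }
  v
}

.syllabify_run <- function(run) {
  chars <- strsplit(run, "", fixed = TRUE)[[1]]
  n <- length(chars)
  v <- .vowel_mask(chars)
  if (!any(v)) return(run) # vowelless run counts as one syllable
  # maximal vowel groups
  r <- rle(v)
  grp_end <- cumsum(r$lengths)
  grp_start <- grp_end - r$lengths + 1L
  vg <- which(r$values)
  gs <- grp_start[vg]
  ge <- grp_end[vg]
  k <- length(gs)
  # silent-e family: merge a final weak group into the previous syllable
  if (k >= 2L) {
    last_s <- gs[k]; last_e <- ge[k]
    tail_str <- substr(run, last_s, n)
    drop <- FALSE
    if (identical(tail_str, "e")) {
      # final lone e: silent, except -le after a consonant (ta-ble)
      if (!(last_s >= 3L && chars[last_s - 1L] == "l" && !v[last_s - 2L] &&
            chars[last_s - 2L] != "l")) {
        drop <- TRUE
      }
    } else if (identical(tail_str, "ed")) {
      # -ed is syllabic only after t or d (decorat-ed, but jump-ed)
      prev <- chars[last_s - 1L]
      if (!prev %in% c("t", "d")) drop <- TRUE
    } else if (identical(tail_str, "es")) {
      # -es is syllabic only after a sibilant (hous-es, but lik-es)
      prev <- chars[last_s - 1L]
      if (!prev %in% c("s", "c", "z", "x", "g", "h")) drop <- TRUE
    }
    if (drop) {
      gs <- gs[-k]; ge <- ge[-k]; k <- k - 1L
    }
  }
  if (k <= 1L) return(run)
  # boundaries: single intervening consonant opens the next syllable,
  # longer clusters split after their first consonant
  cuts <- integer(k - 1L)
  for (i in seq_len(k - 1L)) {
    gap <- gs[i + 1L] - ge[i] - 1L
    cuts[i] <- if (gap <= 1L) gs[i + 1L] - gap else ge[i] + 2L
  }
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, n)
  substring(run, starts, ends)
}

#' Syllabify a word
#'
#' Deterministic orthographic syllabification: vowel groups form nuclei, with
#' silent-e / -ed / -es corrections and an exception table. Joining the
#' returned syllables reproduces the lowercased word.
#'
#' @param word character scalar containing at least one letter.
#' @param language ISO 639-1 code; the rule set is orthography-based and is
#'   applied to all supported Latin-script languages.
#' @return Character vector of syllable strings (length >= 1).
#' @examples
#' syllabify("beautifully") # 4 syllables
#' syllabify("cat")         # "cat"
#' @export
syllabify <- function(word, language = "en") {
  stopifnot(is.character(word), length(word) == 1L)
  w <- tolower(word)
  if (!grepl("\\p{L}", w, perl = TRUE)) {
    cl_abort(sprintf("not a word: '%s' contains no letter", word), "cl_not_a_word")
  }
  hit <- .syllable_exceptions[[w]]
  if (!is.null(hit)) return(hit)
  # split into letter runs; non-letter separators attach to preceding syllable
  pieces <- regmatches(w, gregexpr("\\p{L}+|\\P{L}+", w, perl = TRUE))[[1]]
  out <- character(0)
  prefix <- ""
  for (p in pieces) {
    if (grepl("\\p{L}", p, perl = TRUE)) {
      syl <- .syllabify_run(p)
      if (nzchar(prefix)) {
        syl[1L] <- paste0(prefix, syl[1L])
        prefix <- ""
      }
      out <- c(out, syl)
    } else if (length(out)) {
      out[length(out)] <- paste0(out[length(out)], p)
    } else {
      prefix <- p # leading non-letters (clitic apostrophes) join syllable 1
    }
  }
  out
}

#' Count syllables in a word
#' @inheritParams syllabify
#' @return integer syllable count (>= 1).
#' @export
count_syllables <- function(word, language = "en") {
  length(syllabify(word, language))
}
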