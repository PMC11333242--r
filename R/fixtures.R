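# Synthetic fixture generator. Builds texts from a closed vocabulary with
# hand-verified syllable counts so that the ground-truth readability counts
# (words, sentences, syllables, passives, difficult words) are exact by
# construction, not derived from the pipeline under test.

# closed vocabulary: word -> syllable count (verified against syllabify())
.fixture_vocab <- list(
  nouns = c(cat = 1, dog = 1, bird = 1, fish = 1, house = 1, ball = 1,
    mat = 1, book = 1, tree = 1, road = 1, garden = 2, window = 2,
    teacher = 2, student = 2, morning = 2, banana = 3, elephant = 3,
    piano = 3, tomato = 3, umbrella = 3, helicopter = 4, watermelon = 4),
  verbs_past = c(washed = 1, fixed = 1, cleaned = 1, watched = 1, helped = 1,
    painted = 2, carried = 2, followed = 2, visited = 3, decorated = 4),
  # past participles double as passive forms
  adjectives = c(big = 1, small = 1, red = 1, warm = 1, little = 2,
    yellow = 2, quiet = 2, beautiful = 3, wonderful = 3),
  nonce = c(zorgle = 2, flimp = 1, brastic = 2, quenth = 1, dorfan = 2,
    miggle = 2, trosk = 1, plinder = 2, vrent = 1, shalbo = 2)
)

#' Generate a synthetic fixture text
#'
#' Builds a text of simple transitive sentences (`The <noun> <verb> the
#' <noun>.`) from a closed vocabulary whose syllable structure is known, with
#' a controllable fraction of passive sentences (`The <noun> was <verb> by
#' the <noun>.`) and of out-of-wordlist ("difficult") nonce words. The true
#' counts are returned alongside the text, so metric implementations can be
#' tested against construction-time ground truth. Generation is fully
#' determined by `seed`.
#'
#' @param n_sentences number of sentences (>= 1).
#' @param words_per_sentence approximate sentence length; the transitive
#'   frame has 5 words (6 when passive), and extra slots are filled with
#'   adjectives.
#' @param passive_fraction fraction of sentences in the passive voice (the
#'   passive count is `round(passive_fraction * n_sentences)`).
#' @param difficult_word_fraction fraction of noun slots replaced by nonce
#'   words absent from any wordlist.
#' @param vocabulary_size optional cap on the distinct nouns used.
#' @param seed integer random seed; the same seed yields a byte-identical
#'   text.
#' @return list with `text` (a `raw_text`), and `truth`: `word_count`,
#'   `sentence_count`, `syllable_count`, `passive_sentence_count`,
#'   `difficult_word_count`, `complex_word_count` (words of 3+ syllables)
#'   and the generated `words` per sentence.
#' @export
generate_fixture <- function(n_sentences = 10L, words_per_sentence = 5L,
                             passive_fraction = 0, difficult_word_fraction = 0,
                             vocabulary_size = NULL, seed = 1L) {
  if (n_sentences < 1L || words_per_sentence < 5L) {
    cl_abort("invalid fixture spec: need >= 1 sentence and >= 5 words per sentence",
      "cl_invalid_spec")
  }
  if (passive_fraction < 0 || passive_fraction > 1 ||
      difficult_word_fraction < 0 || difficult_word_fraction > 1) {
    cl_abort("invalid fixture spec: fractions must lie in [0, 1]",
      "cl_invalid_spec")
  }
  vocab <- .fixture_vocab
  if (!is.null(vocabulary_size)) {
    vocab$nouns <- vocab$nouns[seq_len(min(vocabulary_size,
      length(vocab$nouns)))]
  }
  # deterministic linear congruential draws, independent of .Random.seed so
  # fixture generation never perturbs (or is perturbed by) the global RNG
  rng <- local({
    state <- as.double(as.integer(seed))
    function(n) {
      res <- numeric(n)
      for (t in seq_len(n)) {
        state <<- (1103515245 * state + 12345) %% 2^31
        res[t] <- state / 2^31
      }
      res
    }
  })
  n_passive <- round(passive_fraction * n_sentences)
  passive_flags <- c(rep(TRUE, n_passive), rep(FALSE, n_sentences - n_passive))
  draw <- function(pool) {
    names(pool)[floor(rng(1) * length(pool)) + 1L]
  }
  syll_of <- function(w) {
    for (pool in vocab) if (w %in% names(pool)) return(unname(pool[[w]]))
    stop("word outside fixture vocabulary: ", w)
  }
  sentences <- character(n_sentences)
  words_all <- list()
  difficult_total <- 0L
  for (s in seq_len(n_sentences)) {
    subj <- draw(vocab$nouns)
    obj <- draw(vocab$nouns)
    verb <- draw(vocab$verbs_past)
    if (rng(1) < difficult_word_fraction) { subj <- draw(vocab$nonce); difficult_total <- difficult_total + 1L }
    if (rng(1) < difficult_word_fraction) { obj <- draw(vocab$nonce); difficult_total <- difficult_total + 1L }
    extra_slots <- max(0L, words_per_sentence -
        (if (passive_flags[s]) 7L else 5L))
    adjs <- vapply(seq_len(extra_slots), function(z) draw(vocab$adjectives),
      character(1))
    words <- if (passive_flags[s]) {
      c("the", if (length(adjs)) adjs[1], subj, "was", verb, "by", "the",
        if (length(adjs) > 1) adjs[-1], obj)
    } else {
      c("the", if (length(adjs)) adjs[1], subj, verb, "the",
        if (length(adjs) > 1) adjs[-1], obj)
    }
    words[1] <- paste0(toupper(substr(words[1], 1, 1)), substring(words[1], 2))
    sentences[s] <- paste0(paste(words, collapse = " "), ".")
    words_all[[s]] <- tolower(words)
  }
  all_words <- unlist(words_all)
  fn_syll <- c(the = 1, was = 1, by = 1)
  syllables <- vapply(all_words, function(w) {
    if (w %in% names(fn_syll)) unname(fn_syll[[w]]) else syll_of(w)
  }, numeric(1))
  list(
    text = raw_text(paste(sentences, collapse = " "), "en"),
    truth = list(
      word_count = length(all_words),
      sentence_count = n_sentences,
      syllable_count = sum(syllables),
      passive_sentence_count = n_passive,
      difficult_word_count = difficult_total,
      complex_word_count = sum(syllables >= 3),
      types = length(unique(all_words)),
      words = words_all
    )
  )
}

#' Vocabulary of the fixture generator
#'
#' The closed word pools (with known syllable counts) from which
#' [generate_fixture()] builds texts; the `nonce` pool contains the
#' out-of-dictionary words used as "difficult" tokens.
#' @return named list of named numeric vectors (word -> syllables).
#' @export
fixture_vocabulary <- function() .fixture_vocab
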