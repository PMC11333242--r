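test_that("tokenization separates words, punctuation and clitics", {
  toks <- tokenize("The cat sat.")
  expect_equal(toks$surface, c("The", "cat", "sat", "."))
  expect_equal(sum(toks$is_word), 3L)

  toks <- tokenize("My friend's house.")
  expect_true("'s" %in% toks$surface)
  expect_equal(toks$surface[toks$surface == "'s"], "'s")
  d <- annotate("My friend's house is big.")
  clitic <- d$tokens[d$tokens$surface == "'s", ]
  expect_equal(clitic$pos, "PART")
})

test_that("empty or whitespace-only input raises an empty-input error", {
  expect_error(tokenize(""), class = "cl_empty_input")
  expect_error(tokenize("   \n\t "), class = "cl_empty_input")
  expect_error(raw_text(""), class = "cl_empty_input")
})

test_that("unsupported languages are rejected", {
  expect_error(raw_text("bonjour", "xx"), class = "cl_unsupported_language")
  expect_error(annotate(raw_text("hei", "fi")),
    class = "cl_unsupported_language")
})

test_that("detokenization round-trips the input modulo outer whitespace", {
  texts <- c(
    "The cat sat on the mat.",
    "My friend's house is always decorated beautifully.",
    "He said \"yes\"!  Then he left.",
    "Napoleon was the king of France. John ran."
  )
  for (txt in texts) {
    expect_identical(detokenize(annotate(txt)), trimws(txt))
  }
})

test_that("sentence segmentation partitions the token sequence", {
  s <- segment_sentences(tokenize("A. B."))
  expect_equal(nrow(s), 2L)
  s <- segment_sentences(tokenize("just one unterminated clause"))
  expect_equal(nrow(s), 1L)
  s <- segment_sentences(tokenize("The ball was thrown. John ran."))
  expect_equal(nrow(s), 2L)

  # partition property on generated fixtures
  for (seed in 1:5) {
    fx <- generate_fixture(n_sentences = 6L, words_per_sentence = 6L,
      seed = seed)
    doc <- annotate(fx$text)
    spans <- doc$sentences
    expect_equal(spans$start[1L], 1L)
    expect_equal(spans$end[nrow(spans)], nrow(doc$tokens))
    if (nrow(spans) > 1L) {
      expect_equal(spans$start[-1L], spans$end[-nrow(spans)] + 1L)
    }
    # every token belongs to exactly one sentence
    expect_equal(sum(spans$end - spans$start + 1L), nrow(doc$tokens))
  }
})

test_that("syllabification matches reference splits and is total", {
  expect_length(syllabify("beautifully"), 4L)
  expect_length(syllabify("always"), 2L)
  expect_equal(syllabify("cat"), "cat")
  expect_length(syllabify("decorated"), 4L)
  expect_length(syllabify("house"), 1L)
  expect_error(syllabify("1234"), class = "cl_not_a_word")

  # joining syllables yields the lowercased word; count >= 1; deterministic
  words <- c("cat", "House", "beautifully", "decorated", "banana",
    "helicopter", "rhythm", "quiet", "fixed", "painted", "carried",
    "zorgle", "trosk", "little", "yellow", "friend's")
  for (w in words) {
    s1 <- syllabify(w)
    expect_gte(length(s1), 1L)
    expect_identical(paste0(s1, collapse = ""), tolower(w))
    expect_identical(s1, syllabify(w))
  }
})

test_that("fixture vocabulary syllable counts agree with the syllabifier", {
  vocab <- fixture_vocabulary()
  for (pool in vocab) {
    got <- vapply(names(pool), count_syllables, integer(1))
    expect_equal(unname(got), unname(pool))
  }
})

test_that("annotation is deterministic and labels every token", {
  txt <- "The ball was thrown by John. My friend's house is big."
  d1 <- annotate(txt)
  d2 <- annotate(txt)
  expect_identical(d1$tokens, d2$tokens)
  expect_false(any(is.na(d1$tokens$pos)))
  expect_false(any(is.na(d1$tokens$dep)))
  # heads stay within the token's own sentence (root points to itself)
  for (i in seq_len(nrow(d1$tokens))) {
    h <- d1$tokens$head[i]
    expect_equal(d1$tokens$sentence[h], d1$tokens$sentence[i])
  }
})

test_that("passive auxiliary and subject labels mirror clause voice", {
  d <- annotate("The ball was thrown by John.")
  toks <- d$tokens
  expect_equal(toks$dep[toks$surface == "was"], "auxpass")
  expect_equal(toks$dep[toks$surface == "ball"], "nsubjpass")
  d2 <- annotate("John threw the ball.")
  expect_equal(d2$tokens$dep[d2$tokens$surface == "John"], "nsubj")
  expect_false(any(d2$tokens$dep %in% c("auxpass", "nsubjpass")))
})

test_that("a precision request never changes rule-backend output", {
  txt <- "The cat sat on the mat."
  expect_identical(annotate(txt, precision = FALSE)$tokens,
    annotate(txt, precision = TRUE)$tokens)
})
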