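test_that("basic counts use word-token characters", {
  r <- basic_counts("cat sat")
  expect_equal(r$characters, 6)
  expect_equal(r$words, 2)
  expect_equal(r$character_density, 3.0)
  expect_equal(basic_counts("a")$character_density, 1.0)
  fx <- generate_fixture(n_sentences = 2L, words_per_sentence = 5L, seed = 2)
  r <- basic_counts(annotate(fx$text))
  expect_equal(r$mean_sentence_length, r$words / r$sentences)
})

test_that("function/content partition is exhaustive and POS-driven", {
  d <- annotate("The cat sat")
  p <- function_content_partition(d)
  expect_equal(p$function_count, 1)          # the (Determiner)
  expect_equal(p$content_count, 2)           # cat, sat
  expect_equal(p$function_proportion + p$content_proportion, 1)
  # determiners, auxiliaries, pronouns, particles, conjunctions are function
  d2 <- annotate("My friend's house is always decorated beautifully.")
  w <- d2$tokens[d2$tokens$is_word, ]
  fn_pos <- c("ADP", "AUX", "CCONJ", "DET", "INTJ", "PART", "PRON", "SCONJ")
  p2 <- function_content_partition(d2)
  expect_equal(p2$function_count, sum(w$pos %in% fn_pos))
  expect_equal(p2$function_count + p2$content_count, nrow(w))
})

test_that("propositions are extracted per dependency relation and deduplicated", {
  d <- annotate("The cat sat on the mat")
  props <- extract_propositions(d)
  expect_equal(nrow(props), 2L)     # "the cat sat" + "... on the mat"
  expect_equal(pid(d), 2 / 6, tolerance = 1e-9)

  expect_equal(nrow(extract_propositions(annotate("Yes."))), 0L)
  expect_equal(pid(annotate("Yes.")), 0)

  once <- extract_propositions(annotate("The cat sat."))
  twice <- extract_propositions(annotate("The cat sat. The cat sat."))
  expect_equal(twice, once)
})

test_that("PID halves when a text is concatenated with itself", {
  txt <- "The cat sat on the mat. The dog chased the bird."
  single <- annotate(txt)
  doubled <- annotate(paste(txt, txt))
  expect_equal(pid(doubled), pid(single) / 2, tolerance = 1e-9)
})

test_that("diversity measures follow their printed definitions", {
  expect_equal(diversity(letters[1:10])$ttr, 100)
  expect_equal(diversity(letters[1:10])$cttr, 10 / sqrt(20), tolerance = 1e-4)
  expect_equal(diversity(c(letters[1:5], letters[1:5]))$herdan_c,
    log(5) / log(10), tolerance = 1e-9)
  # 200 tokens whose two 100-token segments have TTR 0.8 and 0.6
  seg1 <- c(paste0("w", 1:80), paste0("w", 1:20))
  seg2 <- c(paste0("v", 1:60), paste0("v", 1:40))
  expect_equal(diversity(c(seg1, seg2))$msttr, 0.7, tolerance = 1e-9)
  # maas undefined marker for tiny vocabularies
  expect_true(is.na(diversity(c("a", "a", "b"))$maas))
})

test_that("diversity agrees with a hand-coded oracle on random token vectors", {
  set.seed(7)
  for (k in 1:50) {
    N <- sample(10:500, 1)
    vocab_n <- sample(3:N, 1)
    toks <- sample(paste0("w", seq_len(vocab_n)), N, replace = TRUE)
    got <- diversity(toks)
    want <- oracle_diversity(toks)
    for (m in names(want)) {
      if (is.na(want[[m]])) expect_true(is.na(got[[m]]))
      else expect_equal(got[[m]], want[[m]], tolerance = 1e-9)
    }
  }
})

test_that("TTR is permutation-invariant; MSTTR equals TTR on homogeneous segments", {
  set.seed(99)
  toks <- sample(paste0("w", 1:30), 120, replace = TRUE)
  expect_equal(diversity(toks)$ttr, diversity(sample(toks))$ttr)
  # every segment with identical type count -> msttr equals common segment ttr
  seg <- paste0("w", 1:50)
  toks2 <- c(seg, seg)  # two 50-token segments, each all-distinct
  expect_equal(diversity(toks2, segment_size = 50L)$msttr, 1)
})

test_that("herdan_c lies in (0, 1] whenever 2 <= V <= N", {
  set.seed(13)
  for (k in 1:20) {
    N <- sample(5:200, 1)
    toks <- sample(paste0("w", 1:max(2, N %/% 3)), N, replace = TRUE)
    if (length(unique(toks)) < 2) next
    h <- diversity(toks)$herdan_c
    expect_gt(h, 0)
    expect_lte(h, 1)
  }
})

test_that("the lexical report assembles all components coherently", {
  fx <- generate_fixture(n_sentences = 6L, words_per_sentence = 6L, seed = 5)
  rep <- lexical_report(annotate(fx$text))
  expect_equal(rep$function_count + rep$content_count, rep$words)
  expect_equal(rep$function_proportion + rep$content_proportion, 1)
  expect_equal(rep$pid, rep$unique_propositions / rep$words)
  expect_equal(rep$words, fx$truth$word_count)
  expect_equal(rep$types, fx$truth$types)
  expect_error(lexical_report(""), class = "cl_empty_input")
})
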