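test_that("Flesch Reading Ease follows the printed formula and the 100 cap", {
  r <- flesch_reading_ease(1, 1, 1)
  expect_equal(r$raw, 121.22, tolerance = 1e-9)
  expect_equal(r$score, 100)
  expect_equal(flesch_reading_ease(20, 2, 30)$score, 69.785, tolerance = 1e-9)
  # the paper's easy-sentence example scores high
  rep <- readability("The dog sleeps in the bedroom.")
  expect_gte(rep$flesch_reading_ease, 90)
  expect_error(flesch_reading_ease(0, 1, 0), class = "cl_empty_input")
})

test_that("Flesch-Kincaid grade follows the printed formula, unclamped", {
  expect_equal(flesch_kincaid_grade(1, 1, 1), -3.40, tolerance = 1e-9)
  expect_equal(flesch_kincaid_grade(20, 1, 30), 9.91, tolerance = 1e-9)
  rep <- readability(
    "The industrious professor assessed all student assignments diligently.")
  expect_gt(rep$flesch_kincaid_grade, 12)
})

test_that("Gunning Fog counts three-syllable words as complex", {
  expect_equal(gunning_fog(10, 1, 0), 4.0)
  expect_equal(gunning_fog(10, 1, 2), 12.0)
  expect_equal(readability("The weather today is sunny.")$gunning_fog, 2.0)
})

test_that("Coleman-Liau uses letters and sentences per 100 words", {
  expect_equal(coleman_liau(20, 2, 100), 10.64, tolerance = 1e-9)
  expect_equal(coleman_liau(1, 1, 1), -39.52, tolerance = 1e-9)
  expect_equal(grade_label("coleman_liau", 6), "6th grade / Easy to read")
  expect_equal(grade_label("coleman_liau", 17), "Professional / Very hard")
})

test_that("ARI as printed, with the conventional constant as an option", {
  expect_equal(automated_readability_index(1, 1, 1), 5.21, tolerance = 1e-9)
  expect_equal(automated_readability_index(20, 1, 100), 33.55, tolerance = 1e-9)
  expect_equal(
    automated_readability_index(20, 1, 100, variant = "conventional"),
    33.55 - 21.43, tolerance = 1e-9)
})

test_that("SMOG floors at its additive constant and scales with polysyllables", {
  expect_equal(smog(30, 0), 3.1291)
  expect_equal(smog(30, 30), 8.8419, tolerance = 1e-4)
  expect_gte(smog(7, 3), 3.1291)
})

test_that("Linsear Write applies the r = 20 boundary inclusively", {
  # 100 easy words in 10 sentences -> r = 10 -> 10/2 - 1
  fx <- generate_fixture(n_sentences = 10L, words_per_sentence = 10L, seed = 3)
  stopifnot(fx$truth$word_count == 100L)
  easy <- sum(unlist(lapply(fx$truth$words, function(ws) {
    vapply(ws, function(w) count_syllables(w) <= 2L, logical(1))
  })))
  hard <- 100L - easy
  expect_equal(linsear_write(annotate(fx$text)),
    oracle_linsear(easy, hard, 10L))
  # boundary r exactly 20 and r above 20, via the pure branch arithmetic
  expect_equal(oracle_linsear(20 * 4, 0, 4), 9.0)
  expect_equal(oracle_linsear(80, 20, 4), 17.5)
})

test_that("passive percentage is passive sentences over sentences", {
  expect_equal(passive_percent(
    "The ball was thrown by John. John threw the ball."), 50)
  expect_equal(passive_percent("John ran. Mary slept."), 0)
  fx <- generate_fixture(n_sentences = 4L, passive_fraction = 0.5, seed = 11)
  expect_equal(passive_percent(annotate(fx$text)), 50)
})

test_that("Dale-Chall adjustment is exactly 3.6365 above the 5% threshold", {
  r <- dale_chall(20, 2, 0)
  expect_equal(r$raw, 0.496, tolerance = 1e-9)
  expect_equal(r$adjusted, r$raw)
  r <- dale_chall(20, 2, 4)
  expect_equal(r$raw, 3.654, tolerance = 1e-9)
  expect_equal(r$adjusted, 7.2905, tolerance = 1e-9)
  # discontinuity only at the threshold: 5% exactly is unadjusted
  r5 <- dale_chall(100, 10, 5)
  expect_equal(r5$adjusted, r5$raw)
  r6 <- dale_chall(100, 10, 6)
  expect_equal(r6$adjusted - r6$raw, 3.6365)
})

test_that("difficult words are counted per occurrence against the easy list", {
  expect_equal(difficult_words("the cat purred", c("the", "cat")), 1L)
  expect_equal(difficult_words("zyx zyx", c("other")), 2L)
  expect_equal(difficult_words("The cat", c("the", "cat")), 0L)
})

test_that("grade labels assign boundary scores to the upper band", {
  expect_equal(grade_label("flesch", 95), "5th grade / Very easy to read")
  expect_equal(grade_label("flesch", 55),
    "10th to 12th grade / Fairly difficult to read")
  expect_equal(grade_label("flesch", 90), "5th grade / Very easy to read")
  expect_error(grade_label("smog", 8), class = "cl_unsupported_measure")
})

test_that("syllable count moves Flesch and Flesch-Kincaid in opposite directions", {
  w <- 40; s <- 4
  fre <- vapply(40:80, function(y) flesch_reading_ease(w, s, y)$raw, numeric(1))
  fkg <- vapply(40:80, function(y) flesch_kincaid_grade(w, s, y), numeric(1))
  expect_true(all(diff(fre) < 0))
  expect_true(all(diff(fkg) > 0))
})

test_that("formula implementations match hand-coded oracles on random count tuples", {
  set.seed(42)
  for (k in 1:50) {
    w <- sample(5:400, 1)
    s <- sample(1:20, 1)
    y <- w + sample(0:(2 * w), 1)     # syllables >= words
    l <- round(w * runif(1, 2.5, 7))  # letters
    ch <- l + sample(0:10, 1)         # characters
    cx <- sample(0:w, 1)              # complex words
    diff_w <- sample(0:w, 1)
    expect_equal(flesch_reading_ease(w, s, y)$raw, oracle_fre(w, s, y),
      tolerance = 1e-9)
    expect_equal(flesch_kincaid_grade(w, s, y), oracle_fkg(w, s, y),
      tolerance = 1e-9)
    expect_equal(gunning_fog(w, s, cx), oracle_fog(w, s, cx), tolerance = 1e-9)
    expect_equal(coleman_liau(w, s, l), oracle_cli(w, s, l), tolerance = 1e-9)
    expect_equal(automated_readability_index(w, s, ch), oracle_ari(w, s, ch),
      tolerance = 1e-9)
    expect_equal(smog(s, cx), oracle_smog(s, cx), tolerance = 1e-9)
    dc <- dale_chall(w, s, diff_w)
    odc <- oracle_dale_chall(w, s, diff_w)
    expect_equal(dc$raw, unname(odc["raw"]), tolerance = 1e-9)
    expect_equal(dc$adjusted, unname(odc["adjusted"]), tolerance = 1e-9)
  }
})

test_that("the document-level report is consistent with fixture ground truth", {
  fx <- generate_fixture(n_sentences = 8L, words_per_sentence = 7L,
    passive_fraction = 0.25, difficult_word_fraction = 0.3, seed = 19)
  doc <- annotate(fx$text)
  counts <- readability_counts(doc)
  expect_equal(counts$word_count, fx$truth$word_count)
  expect_equal(counts$sentence_count, fx$truth$sentence_count)
  expect_equal(counts$syllable_count, fx$truth$syllable_count)
  expect_equal(counts$passive_sentence_count, fx$truth$passive_sentence_count)
  expect_equal(counts$difficult_word_count, fx$truth$difficult_word_count)
  expect_equal(counts$complex_word_count, fx$truth$complex_word_count)
  rep <- readability(doc)
  expect_equal(rep$flesch_reading_ease_raw,
    oracle_fre(counts$word_count, counts$sentence_count,
      counts$syllable_count), tolerance = 1e-9)
  expect_lte(rep$flesch_reading_ease, 100)
})
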