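test_that("fixture generation is seed-deterministic with exact ground truth", {
  a <- generate_fixture(n_sentences = 5L, words_per_sentence = 6L,
    passive_fraction = 0.4, difficult_word_fraction = 0.2, seed = 101)
  b <- generate_fixture(n_sentences = 5L, words_per_sentence = 6L,
    passive_fraction = 0.4, difficult_word_fraction = 0.2, seed = 101)
  expect_identical(a$text$content, b$text$content)
  expect_equal(a$truth$passive_sentence_count, 2L)
  expect_error(generate_fixture(passive_fraction = 1.5),
    class = "cl_invalid_spec")
  expect_error(generate_fixture(n_sentences = 0L), class = "cl_invalid_spec")
  # all-unique vocabulary draw yields TTR 100 via the pipeline
  small <- generate_fixture(n_sentences = 1L, words_per_sentence = 5L,
    seed = 3)
  if (small$truth$types == small$truth$word_count) {
    expect_equal(diversity(annotate(small$text))$ttr, 100)
  }
})

test_that("text files read identically with LF and CRLF endings", {
  lf <- withr::local_tempfile(fileext = ".txt")
  crlf <- withr::local_tempfile(fileext = ".txt")
  writeLines("The cat sat.\nThe dog ran.", lf, sep = "\n")
  con <- file(crlf, open = "wb")
  writeBin(charToRaw("The cat sat.\r\nThe dog ran.\r\n"), con)
  close(con)
  t1 <- annotate(read_text(lf))
  t2 <- annotate(read_text(crlf))
  expect_equal(t1$tokens$surface, t2$tokens$surface)
})

test_that("report tables round-trip through csv and json writers", {
  tab <- data.frame(measure = c("ttr", "pid"), value = c(83.3, 0.33))
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_report(tab, path)
    back <- if (ext == ".csv") {
      utils::read.csv(path, stringsAsFactors = FALSE)
    } else {
      as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
    }
    expect_equal(back$measure, tab$measure)
    expect_equal(back$value, tab$value, tolerance = 1e-12)
  }
  expect_error(write_report(tab, "x.xyz"), class = "cl_file_format_error")
})

test_that("batch analysis emits one row per document with stable columns", {
  t1 <- withr::local_tempfile(fileext = ".txt")
  t2 <- withr::local_tempfile(fileext = ".txt")
  t3 <- withr::local_tempfile(fileext = ".txt")
  writeLines("The cat sat on the mat. The dog ran.", t1)
  writeLines("The ball was thrown by John.", t2)
  writeLines("", t3)
  out <- analyze_batch(c(t1, t2, t3))
  expect_equal(nrow(out), 3L)
  expect_equal(out$status[1:2], c("ok", "ok"))
  expect_match(out$status[3], "^error")
  expect_true(all(is.na(out[3, -(1:2)])))
  # error rows do not shrink the column set
  expect_identical(names(analyze_batch(c(t1, t2))), names(out))
  # determinism
  expect_identical(analyze_batch(c(t1, t2, t3)), out)
  expect_error(analyze_batch(character(0)), class = "cl_empty_batch")
  expect_error(analyze_batch(c(t3)), class = "cl_empty_batch")
})

test_that("batch rows equal direct per-document measure calls", {
  txt <- "The ball was thrown by John. My friend's house is big."
  out <- analyze_batch(list(txt))
  doc <- annotate(txt)
  rb <- readability(doc)
  lx <- lexical_report(doc)
  expect_equal(out$readability.flesch_reading_ease, rb$flesch_reading_ease)
  expect_equal(out$readability.passive_percent, rb$passive_percent)
  expect_equal(out$lexical.pid, lx$pid)
  expect_equal(out$lexical.ttr, lx$ttr)
  expect_equal(out$phonology.syllable_word_ratio,
    phonology_report(doc)$syllable_word_ratio)
})
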