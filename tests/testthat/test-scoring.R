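test_that("edit scripts reproduce canonical examples", {
  s <- edit_script("boat", "boat")
  expect_equal(s$distance, 0)
  expect_equal(sum(s$counts), 0)

  s <- edit_script("cat", "cta")
  expect_equal(s$distance, 1)
  expect_equal(unname(s$counts["transpositions"]), 1L)

  s <- edit_script("house", "hose")
  expect_equal(s$distance, 1)
  expect_equal(unname(s$counts["deletions"]), 1L)

  s <- edit_script("", "ab")
  expect_equal(s$distance, 2)
  expect_equal(unname(s$counts["insertions"]), 2L)

  s <- edit_script("yacht", "yat")
  expect_equal(s$distance, 2)
  expect_equal(unname(s$counts["deletions"]), 2L)

  s <- edit_script("from", "form")
  expect_equal(s$distance, 1)
  expect_equal(unname(s$counts["transpositions"]), 1L)
})

test_that("distance and decomposition match the brute-force oracle exhaustively", {
  strings <- all_strings(c("a", "b", "c"), 3L)  # all pairs up to length 3
  for (t in strings) {
    for (r in strings) {
      got <- edit_script(t, r)
      want <- osa_oracle(t, r)
      expect_identical(as.integer(got$distance), as.integer(want$distance))
      expect_equal(sum(got$counts), got$distance)
      decomp <- unname(got$counts[c("insertions", "deletions",
        "substitutions", "transpositions")])
      ok <- any(vapply(want$decompositions,
        function(v) all(v == decomp), logical(1)))
      expect_true(ok, info = sprintf("'%s' -> '%s'", t, r))
    }
  }
})

test_that("edit distance is a metric and swaps ins/del under reversal", {
  set.seed(17)
  alphabet <- c("a", "b", "c")
  rand_str <- function() {
    paste0(sample(alphabet, sample(0:5, 1), replace = TRUE), collapse = "")
  }
  for (k in 1:200) {
    x <- rand_str(); y <- rand_str(); z <- rand_str()
    dxy <- edit_script(x, y)$distance
    dyx <- edit_script(y, x)$distance
    expect_identical(dxy, dyx)
    expect_identical(edit_script(x, x)$distance, 0L)
    # triangle inequality (holds for OSA on these short random triples)
    expect_lte(dxy, edit_script(x, z)$distance + edit_script(z, y)$distance)
    # reversal swaps insertions and deletions, preserves the rest
    cf <- edit_script(x, y)$counts
    cb <- edit_script(y, x)$counts
    expect_equal(unname(cf["insertions"]), unname(cb["deletions"]))
    expect_equal(unname(cf["deletions"]), unname(cb["insertions"]))
    expect_equal(unname(cf["substitutions"]), unname(cb["substitutions"]))
    expect_equal(unname(cf["transpositions"]), unname(cb["transpositions"]))
  }
})

test_that("word-mode scoring is letter-based, case-folded", {
  row <- spell_score_word("boat", "boat")
  expect_equal(row$similarity, 1.0)
  row <- spell_score_word("yacht", "yat")
  expect_equal(row$distance, 2L)
  expect_equal(row$deletions, 2L)
  row <- spell_score_word("from", "form")
  expect_equal(row$distance, 1L)
  expect_equal(row$transpositions, 1L)
  expect_equal(spell_score_word("Boat", "boat")$distance, 0L)
  expect_error(spell_score_word("", "x"), class = "cl_missing_value")
  # error decomposition always sums to the distance
  expect_equal(row$insertions + row$deletions + row$substitutions +
      row$transpositions, row$distance)
})

test_that("nonword mode compares phoneme sequences, not spellings", {
  row <- spell_score_nonword("dake", "daik")
  expect_equal(row$distance, 0L)
  expect_equal(row$similarity, 1.0)
  # the same pair in word (letter) mode is penalized
  expect_gt(spell_score_word("dake", "daik")$distance, 0L)
  row2 <- spell_score_nonword("dake", "take")
  expect_equal(row2$distance, 1L)
  expect_equal(row2$substitutions, 1L)
})

test_that("phonology scoring decomposes phonemic errors", {
  expect_equal(phonology_score("cat", "cat")$similarity, 1.0)
  row <- phonology_score("cat", "cats")
  expect_equal(row$insertions, 1L)
  expect_equal(row$distance, 1L)
  row2 <- phonology_score("cat", "tack")
  expect_equal(row2$distance, 2L)
  expect_equal(row2$substitutions, 2L)
  expect_equal(row2$mode, "phoneme")
})

test_that("batch scoring preserves order, flags bad rows, and is deterministic", {
  tab <- data.frame(
    target = c("boat", "from", "yacht", "house"),
    response = c("boat", "form", "", "house"),
    stringsAsFactors = FALSE
  )
  out <- batch_score(tab, mode = "word")
  expect_equal(nrow(out), 4L)
  expect_equal(out$status, c("ok", "ok", "missing_value", "ok"))
  s <- attr(out, "summary")
  expect_equal(s$n_scored, 3L)
  expect_equal(s$n_flagged, 1L)
  expect_equal(s$mean_similarity, mean(out$similarity[out$status == "ok"]))
  expect_identical(batch_score(tab, mode = "word"), out)

  same <- data.frame(target = rep("cat", 3), response = rep("cat", 3))
  expect_equal(attr(batch_score(same, mode = "word"), "summary")$mean_similarity, 1)

  expect_error(batch_score(data.frame(a = 1), mode = "word"),
    class = "cl_schema_error")
})

test_that("pair tables load from CSV with configurable column names", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(Target = c("boat", "from"), Answer = c("boat", "form")),
    path, row.names = FALSE)
  tab <- read_pairs_table(path, target_col = "Target", response_col = "Answer")
  expect_equal(tab$target, c("boat", "from"))
  out <- batch_score(tab, mode = "word")
  expect_equal(out$distance, c(0L, 1L))
  expect_error(read_pairs_table(path), class = "cl_schema_error")
})
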