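# Restricted Damerau-Levenshtein (optimal string alignment) edit scripts over
# arbitrary symbol sequences (letters or IPA segments): unit-cost insertions,
# deletions, substitutions, and adjacent transpositions, with each substring
# edited at most once. The backtrace is deterministic: at equal cost it
# prefers match > substitution > transposition > deletion > insertion,
# scanning from the sequence ends, so per-error-type counts are reproducible.

as_symbols <- function(x) {
  if (length(x) == 1L && is.character(x)) {
    if (is.na(x)) return(character(0))
    return(strsplit(x, "", fixed = TRUE)[[1]])
  }
  as.character(x)
}

#' Edit script between two symbol sequences
#'
#' Computes the minimal optimal-string-alignment Damerau-Levenshtein edit
#' script transforming `target` into `response`. Character scalars are split
#' into letters; character vectors are treated as pre-segmented symbol
#' sequences (e.g. IPA segments).
#'
#' @param target,response character scalar (split into characters) or
#'   character vector of symbols. Empty sequences are allowed.
#' @return An object of class `edit_script`: list with `distance`, `counts`
#'   (named: insertions, deletions, substitutions, transpositions; they sum
#'   to `distance`), and `operations`, a data.frame of aligned operations
#'   (`op`, `target_pos`, `response_pos`, `target_sym`, `response_sym`).
#' @examples
#' edit_script("from", "form")   # one transposition
#' edit_script("yacht", "yat")   # two deletions
#' @export
edit_script <- function(target, response) {
  a <- as_symbols(target)
  b <- as_symbols(response)
  n <- length(a)
  m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  if (n > 0L && m > 0L) {
    for (i in 1:n) {
      for (j in 1:m) {
        cost <- if (a[i] == b[j]) 0L else 1L
        best <- min(D[i, j] + cost, D[i, j + 1L] + 1L, D[i + 1L, j] + 1L)
        if (i > 1L && j > 1L && a[i] == b[j - 1L] && a[i - 1L] == b[j]) {
          best <- min(best, D[i - 1L, j - 1L] + 1L)
        }
        D[i + 1L, j + 1L] <- best
      }
    }
  }
  # deterministic backtrace from the end
  ops <- list()
  i <- n; j <- m
  push <- function(op, ti, rj) {
    ops[[length(ops) + 1L]] <<- data.frame(
      op = op,
      target_pos = if (is.na(ti)) NA_integer_ else ti,
      response_pos = if (is.na(rj)) NA_integer_ else rj,
      target_sym = if (is.na(ti)) NA_character_ else a[ti],
      response_sym = if (is.na(rj)) NA_character_ else b[rj],
      stringsAsFactors = FALSE
    )
  }
  while (i > 0L || j > 0L) {
    here <- D[i + 1L, j + 1L]
    if (i > 0L && j > 0L && a[i] == b[j] && here == D[i, j]) {
      push("match", i, j); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && j > 0L && a[i] != b[j] && here == D[i, j] + 1L) {
      push("substitution", i, j); i <- i - 1L; j <- j - 1L
    } else if (i > 1L && j > 1L && a[i] == b[j - 1L] && a[i - 1L] == b[j] &&
        a[i] != b[j] && here == D[i - 1L, j - 1L] + 1L) {
      push("transposition", i, j); i <- i - 2L; j <- j - 2L
    } else if (i > 0L && here == D[i, j + 1L] + 1L) {
      push("deletion", i, NA); i <- i - 1L
    } else {
      push("insertion", NA, j); j <- j - 1L
    }
  }
  operations <- if (length(ops)) {
    do.call(rbind, rev(ops))
  } else {
    data.frame(op = character(0), target_pos = integer(0),
      response_pos = integer(0), target_sym = character(0),
      response_sym = character(0))
  }
  counts <- c(
    insertions = sum(operations$op == "insertion"),
    deletions = sum(operations$op == "deletion"),
    substitutions = sum(operations$op == "substitution"),
    transpositions = sum(operations$op == "transposition")
  )
  structure(
    list(distance = D[n + 1L, m + 1L], counts = counts,
      operations = operations, target = a, response = b),
    class = "edit_script"
  )
}

#' @export
print.edit_script <- function(x, ...) {
  cat(sprintf("Edit script: distance %d (%s)\n", x$distance,
    paste(sprintf("%s %d", sub("s$", "", names(x$counts)), x$counts),
      collapse = ", ")))
  print(x$operations)
  invisible(x)
}

# assemble one ScoreRow from an edit script
.score_row <- function(target, response, script, mode, status = "ok") {
  len <- max(length(script$target), length(script$response))
  data.frame(
    target = if (is.character(target) && length(target) == 1L) target
      else paste(target, collapse = " "),
    response = if (is.character(response) && length(response) == 1L) response
      else paste(response, collapse = " "),
    mode = mode,
    distance = script$distance,
    similarity = if (len > 0L) 1 - script$distance / len else 1,
    insertions = unname(script$counts["insertions"]),
    deletions = unname(script$counts["deletions"]),
    substitutions = unname(script$counts["substitutions"]),
    transpositions = unname(script$counts["transpositions"]),
    status = status,
    stringsAsFactors = FALSE
  )
}

.blank_row <- function(target, response, mode, status) {
  data.frame(target = target, response = response, mode = mode,
    distance = NA_integer_, similarity = NA_real_, insertions = NA_integer_,
    deletions = NA_integer_, substitutions = NA_integer_,
    transpositions = NA_integer_, status = status, stringsAsFactors = FALSE)
}

#' Score a spelled word against its target (word mode)
#'
#' Letter-by-letter comparison after case folding; accents are preserved.
#' The composite similarity is `1 - distance / max(letter lengths)`, in
#' `[0, 1]`, and the error decomposition (insertions, deletions,
#' substitutions, transpositions) sums to the distance. Substitution counts
#' are also what clinical scoring sheets label "inversions".
#'
#' @param target,response character scalars.
#' @param language ISO 639-1 code (recorded; letter comparison is
#'   language-independent).
#' @return one-row data.frame (a ScoreRow).
#' @export
spell_score_word <- function(target, response, language = "en") {
  target <- trimws(target); response <- trimws(response)
  if (!nzchar(target) || !nzchar(response) || is.na(target) || is.na(response)) {
    cl_abort("empty target or response", "cl_missing_value")
  }
  script <- edit_script(tolower(target), tolower(response))
  .score_row(target, response, script, "word")
}

#' Score a spelled non-word against its target (phonemic mode)
#'
#' Non-words have no conventional orthography, so both strings are converted
#' to IPA phoneme sequences first and the edit script is computed over
#' phoneme segments: homophonic spellings of the same non-word score a
#' distance of 0.
#'
#' @inheritParams spell_score_word
#' @param backend G2P backend (see [g2p_backends()]).
#' @return one-row data.frame (a ScoreRow) with lengths in phonemes.
#' @export
spell_score_nonword <- function(target, response, language = "en",
                                backend = "rule_g2p_en") {
  target <- trimws(target); response <- trimws(response)
  if (!nzchar(target) || !nzchar(response) || is.na(target) || is.na(response)) {
    cl_abort("empty target or response", "cl_missing_value")
  }
  be <- resolve_g2p(backend)
  if (!language %in% be$languages) cl_unsupported_language(language)
  script <- edit_script(be$convert(tolower(target), language),
    be$convert(tolower(response), language))
  .score_row(target, response, script, "nonword")
}

#' Score a produced word against its target phonologically
#'
#' Converts target and response to IPA and compares the phoneme sequences:
#' the composite phonemic score (normalized similarity) plus counts of
#' phonemic deletions, insertions, transpositions, and substitutions.
#'
#' @inheritParams spell_score_nonword
#' @return one-row data.frame (a ScoreRow) in phoneme units.
#' @export
phonology_score <- function(target, response, language = "en",
                            backend = "rule_g2p_en") {
  row <- spell_score_nonword(target, response, language, backend)
  row$mode <- "phoneme"
  row
}

#' Score a batch of target/response pairs
#'
#' Applies the selected scorer to every row of a pair table, preserving
#' order. Rows with an empty target or response are flagged
#' (`status = "missing_value"`) and carried through with NA scores rather
#' than dropped. A summary with the mean distance and mean similarity over
#' scored rows is attached as the `"summary"` attribute.
#'
#' @param table data.frame with `target` and `response` columns, or a path
#'   accepted by [read_pairs_table()].
#' @param mode `"word"`, `"nonword"`, or `"phoneme"`.
#' @param language ISO 639-1 code.
#' @param target_col,response_col column names when `table` is a path.
#' @return data.frame of ScoreRows (class `score_table`) with attribute
#'   `summary`.
#' @export
batch_score <- function(table, mode = c("word", "nonword", "phoneme"),
                        language = "en", target_col = "target",
                        response_col = "response") {
  mode <- match.arg(mode)
  if (is.character(table) && length(table) == 1L) {
    table <- read_pairs_table(table, target_col, response_col)
  }
  for (col in c("target", "response")) {
    if (!col %in% names(table)) {
      cl_abort(sprintf("pairs table is missing required column '%s'", col),
        "cl_schema_error")
    }
  }
  scorer <- switch(mode,
    word = function(t, r) spell_score_word(t, r, language),
    nonword = function(t, r) spell_score_nonword(t, r, language),
    phoneme = function(t, r) phonology_score(t, r, language)
  )
  rows <- lapply(seq_len(nrow(table)), function(i) {
    t <- table$target[i]; r <- table$response[i]
    bad <- is.na(t) || is.na(r) || !nzchar(trimws(t)) || !nzchar(trimws(r))
    if (bad) {
      return(.blank_row(ifelse(is.na(t), "", t), ifelse(is.na(r), "", r),
        mode, "missing_value"))
    }
    scorer(t, r)
  })
  out <- do.call(rbind, rows)
  ok <- out$status == "ok"
  attr(out, "summary") <- list(
    n = nrow(out),
    n_scored = sum(ok),
    n_flagged = sum(!ok),
    mean_distance = if (any(ok)) mean(out$distance[ok]) else NA_real_,
    mean_similarity = if (any(ok)) mean(out$similarity[ok]) else NA_real_
  )
  class(out) <- c("score_table", "data.frame")
  out
}

#' @export
print.score_table <- function(x, ...) {
  s <- attr(x, "summary")
  NextMethod()
  cat(sprintf(
    "-- %d rows (%d scored, %d flagged); mean distance %.3f, mean similarity %.3f\n",
    s$n, s$n_scored, s$n_flagged, s$mean_distance, s$mean_similarity))
  invisible(x)
}
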