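# Batch document analysis: one feature row per document, with stable
# `<module>.<measure>` column names for longitudinal comparability.

.feature_schema_version <- "1"

# paste0 recycles zero-length vectors to "", so prefix explicitly
.prefixed <- function(prefix, x) {
  nm <- names(x)
  if (is.null(nm) || length(nm) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  stats::setNames(as.numeric(x), paste0(prefix, nm))
}

# flatten one document's full measure battery into a named numeric vector
.document_features <- function(doc, easy_words, dictionary, segment_size) {
  rb <- readability(doc, easy_words)
  lx <- lexical_report(doc, segment_size = segment_size)
  ph <- phonology_report(doc)
  posd <- pos_distribution(doc, display = FALSE)
  cons <- constituent_counts(doc)
  ents <- entity_distribution(doc)
  flags <- detect_sentence_issues(doc)
  nonwords <- detect_nonwords(doc, dictionary)
  read_keys <- c("flesch_reading_ease", "flesch_reading_ease_raw",
    "flesch_kincaid_grade", "gunning_fog", "coleman_liau",
    "automated_readability_index", "smog", "linsear_write",
    "passive_percent", "dale_chall_raw", "dale_chall_adjusted",
    "difficult_words")
  lex_keys <- c("characters", "character_density", "words", "sentences",
    "mean_sentence_length", "function_word_count" = "function_count",
    "function_word_proportion" = "function_proportion",
    "content_word_count" = "content_count",
    "content_word_proportion" = "content_proportion",
    "unique_propositions", "pid", "ttr", "cttr", "maas", "msttr", "herdan_c")
  out <- c(
    stats::setNames(
      vapply(read_keys, function(k) as.numeric(rb[[k]]), numeric(1)),
      paste0("readability.", read_keys)),
    stats::setNames(
      vapply(seq_along(lex_keys), function(i) as.numeric(lx[[lex_keys[i]]]),
        numeric(1)),
      paste0("lexical.", ifelse(nzchar(names(lex_keys)), names(lex_keys),
        lex_keys))),
    stats::setNames(
      c(ph$syllable_count, ph$syllable_word_ratio),
      c("phonology.syllable_count", "phonology.syllable_word_ratio")),
    .prefixed("morphology.pos_", stats::setNames(as.numeric(posd$counts),
      tolower(names(posd$counts)))),
    .prefixed("syntax.", cons$counts),
    .prefixed("semantics.entity_", stats::setNames(as.numeric(ents$counts),
      tolower(names(ents$counts)))),
    c(
      "grammar.fragment_flags" = sum(flags$kind == "fragment"),
      "grammar.run_on_flags" = sum(flags$kind == "run_on"),
      "grammar.complex_sentence_flags" = sum(flags$kind == "complex_sentence"),
      "grammar.nonword_flags" = nrow(nonwords),
      "grammar.hapax_nonwords" = sum(nonwords$hapax)
    )
  )
  out
}

#' Analyze a batch of documents
#'
#' Runs the full measure battery (readability, lexical, phonology,
#' morphosyntax, semantics, grammar flags) over one or more text files or
#' documents and returns one feature row per document. Per-document failures
#' (e.g. an empty file) are recorded as error rows with NA features; the
#' batch never aborts. Column names are `<module>.<measure>`; distribution
#' columns (POS, entities) vary with the observed categories, but within one
#' batch every row has the identical column set, with zeros for categories a
#' document lacks.
#'
#' @param paths character vector of text-file paths, or a list of
#'   `annotated_document` / `raw_text` / character inputs.
#' @param language ISO 639-1 code for file inputs.
#' @param easy_words,dictionary wordlists (vector or path; `NULL` = bundled).
#' @param segment_size MSTTR segment size.
#' @return data.frame with `document_id`, `status`, and feature columns;
#'   attribute `schema_version`.
#' @export
analyze_batch <- function(paths, language = "en", easy_words = NULL,
                          dictionary = NULL, segment_size = 100L) {
  if (length(paths) == 0L) {
    cl_abort("empty batch: no inputs given", "cl_empty_batch")
  }
  ids <- if (is.character(paths)) basename(paths) else
    paste0("doc", seq_along(paths))
  features <- vector("list", length(paths))
  status <- character(length(paths))
  for (i in seq_along(paths)) {
    res <- tryCatch({
      doc <- if (is.character(paths)) {
        as_document(read_text(paths[[i]], language))
      } else {
        as_document(paths[[i]], language)
      }
      .document_features(doc, easy_words, dictionary, segment_size)
    }, clinlang_error = function(e) e, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- paste0("error: ", conditionMessage(res))
      features[[i]] <- stats::setNames(numeric(0), character(0))
    } else {
      status[i] <- "ok"
      features[[i]] <- res
    }
  }
  if (!any(status == "ok")) {
    cl_abort("empty batch: no input could be analyzed", "cl_empty_batch")
  }
  all_cols <- unique(unlist(lapply(features, names)))
  rows <- lapply(seq_along(features), function(i) {
    v <- stats::setNames(rep(NA_real_, length(all_cols)), all_cols)
    if (status[i] == "ok") {
      v[] <- 0
      v[names(features[[i]])] <- features[[i]]
    }
    v
  })
  out <- cbind(
    data.frame(document_id = ids, status = status, stringsAsFactors = FALSE),
    as.data.frame(do.call(rbind, rows))
  )
  attr(out, "schema_version") <- .feature_schema_version
  out
}
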