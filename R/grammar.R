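# Heuristic grammar-error flags: sentence-level structure issues (fragments,
# run-ons, heavy subordination) and dictionary-based nonword detection with a
# paraphasia/neologism split by edit distance.

.finite_detail <- c("Verb, Past Tense", "Verb, 3Rd Person Singular Present",
  "Verb, Non-3Rd Person Singular Present", "Verb, Base Form")

# finite clause heads inside a sentence slice: verbs that are not bare
# participles (a participle with a passive/perfect auxiliary counts, via the
# auxiliary's finiteness)
.finite_clauses <- function(pos, detail, dep, lower) {
  verbs <- which(pos == "VERB")
  vapply(verbs, function(v) {
    if (detail[v] %in% .finite_detail) return(TRUE)
    any(dep == "auxpass" | dep == "aux") || any(pos == "AUX")
  }, logical(1)) |> (\(ok) verbs[ok])()
}

#' Detect sentence-level grammar issues
#'
#' Flags three heuristic patterns per sentence:
#' * `fragment` - the root is not a finite verb (or finite copular clause)
#'   and no subject + predicate pair exists;
#' * `run_on` - two or more independent finite clauses joined without a
#'   coordinating conjunction or separating punctuation;
#' * `complex_sentence` - at least `complex_threshold` subordinate clauses.
#'
#' @param doc an annotated document (or text).
#' @param complex_threshold subordinate-clause count that triggers a
#'   `complex_sentence` flag (default 3).
#' @return data.frame with columns `kind`, `sentence`, `detail`; zero rows
#'   when nothing is flagged.
#' @export
detect_sentence_issues <- function(doc, complex_threshold = 3L) {
  doc <- as_document(doc)
  toks <- doc$tokens
  if (is.null(toks$dep)) cl_missing_annotation("dependency labels")
  flags <- list()
  for (s in seq_len(nrow(doc$sentences))) {
    idx <- seq(doc$sentences$start[s], doc$sentences$end[s])
    pos <- toks$pos[idx]; detail <- toks$pos_detail[idx]
    dep <- toks$dep[idx]; lower <- toks$lower[idx]
    root_local <- which(dep == "root")[1L]
    finite <- .finite_clauses(pos, detail, dep, lower)
    has_subject <- any(dep %in% c("nsubj", "nsubjpass"))
    has_predicate <- any(pos %in% c("VERB", "AUX")) ||
      (any(dep == "cop"))
    root_is_finite_verb <- !is.na(root_local) &&
      (pos[root_local] %in% c("VERB", "AUX") || any(dep == "cop"))
    if (!root_is_finite_verb && !(has_subject && has_predicate)) {
      flags[[length(flags) + 1L]] <- data.frame(kind = "fragment",
        sentence = s, detail = "no finite root clause with subject and predicate")
    }
    # run-on: >= 2 finite clauses each with its own subject, no coordinating
    # conjunction and no internal punctuation between them
    subj_heads <- toks$head[idx][dep %in% c("nsubj", "nsubjpass")]
    clause_heads <- unique(subj_heads)
    if (length(clause_heads) >= 2L) {
      has_cc <- any(pos == "CCONJ")
      internal_punct <- any(lower %in% c(",", ";", ":", "-", "--") )
      has_mark <- any(dep %in% c("mark")) || any(pos == "SCONJ") ||
        any(dep == "relcl")
      if (!has_cc && !internal_punct && !has_mark) {
        flags[[length(flags) + 1L]] <- data.frame(kind = "run_on",
          sentence = s,
          detail = sprintf("%d independent clauses without conjunction or punctuation",
            length(clause_heads)))
      }
    }
    n_sub <- sum(dep %in% c("advcl", "ccomp", "xcomp", "relcl", "acl"))
    if (n_sub >= complex_threshold) {
      flags[[length(flags) + 1L]] <- data.frame(kind = "complex_sentence",
        sentence = s, detail = sprintf("%d subordinate clauses", n_sub))
    }
  }
  if (!length(flags)) {
    return(data.frame(kind = character(0), sentence = integer(0),
      detail = character(0)))
  }
  do.call(rbind, flags)
}

#' Detect nonwords (neologism / paraphasia candidates)
#'
#' Flags word tokens absent from a reference dictionary. A nonword within
#' edit distance `paraphasia_distance` (restricted Damerau-Levenshtein) of
#' some dictionary word is labelled a phonemic-paraphasia candidate; others
#' are labelled neologisms. Tokens that occur exactly once in the document
#' are additionally marked as hapax legomena.
#'
#' @param doc an annotated document (or text).
#' @param dictionary character vector of words or a wordlist path; `NULL`
#'   loads the bundled English dictionary.
#' @param paraphasia_distance edit-distance threshold for the paraphasia /
#'   neologism split (default 2).
#' @return data.frame with columns `kind` (`"nonword"`), `token`, `surface`,
#'   `subtype` (`"paraphasia_candidate"` or `"neologism"`), `hapax`,
#'   `nearest` (closest dictionary word for paraphasia candidates, else NA).
#' @export
detect_nonwords <- function(doc, dictionary = NULL, paraphasia_distance = 2L) {
  doc <- as_document(doc)
  dict <- as_wordlist(dictionary, default = "dictionary_en.txt")
  toks <- doc$tokens
  word_idx <- which(toks$is_word & toks$letter_count > 0L &
      !grepl("^[0-9]", toks$surface))
  lower <- tolower(toks$surface[word_idx])
  miss <- which(!lower %in% dict & !lower %in% c("'s", "’s", "n't"))
  if (!length(miss)) {
    return(data.frame(kind = character(0), token = integer(0),
      surface = character(0), subtype = character(0), hapax = logical(0),
      nearest = character(0)))
  }
  freq <- table(lower)
  out <- lapply(miss, function(i) {
    w <- lower[i]
    # restrict the scan to similar-length dictionary entries
    cand <- dict[abs(nchar(dict) - nchar(w)) <= paraphasia_distance]
    dists <- vapply(cand, function(d) edit_script(w, d)$distance, numeric(1))
    best <- if (length(dists)) which.min(dists) else integer(0)
    is_para <- length(best) && dists[best] <= paraphasia_distance
    data.frame(
      kind = "nonword",
      token = word_idx[i],
      surface = toks$surface[word_idx[i]],
      subtype = if (is_para) "paraphasia_candidate" else "neologism",
      hapax = unname(freq[w] == 1L),
      nearest = if (is_para) cand[best] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
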