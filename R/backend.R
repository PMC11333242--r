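# Pluggable annotation backends. A backend is a list with fields
#   name       backend identifier
#   languages  ISO codes it can annotate
#   annotate   function(tokens, sentences, language, precision) -> tokens with
#              lemma / pos / pos_detail / dep / head / entity columns added
# The bundled "rule_en" backend is a deterministic lexicon + suffix-heuristic
# tagger with a rule-based dependency pass; it needs no external models, so the
# whole pipeline runs offline and reproducibly. An adapter for an industrial
# parser can be plugged in through register_annotation_backend() without
# touching any metric code.

.backend_registry <- new.env(parent = emptyenv())

#' Register an annotation backend
#'
#' @param backend list with `name`, `languages`, and `annotate(tokens,
#'   sentences, language, precision)`.
#' @export
register_annotation_backend <- function(backend) {
  stopifnot(is.list(backend), is.character(backend$name),
    is.function(backend$annotate))
  assign(backend$name, backend, envir = .backend_registry)
  invisible(backend$name)
}

#' List registered annotation backends
#' @return character vector of backend names.
#' @export
annotation_backends <- function() ls(.backend_registry)

resolve_backend <- function(backend) {
  if (is.list(backend)) return(backend)
  if (!exists(backend, envir = .backend_registry)) {
    cl_abort(sprintf("annotation backend '%s' is not registered", backend),
      "cl_backend_error")
  }
  get(backend, envir = .backend_registry)
}

# ---- lexicons for the English rule backend ---------------------------------

.lex <- new.env(parent = emptyenv())

.lex$det <- c("the", "a", "an", "this", "that", "these", "those", "each",
  "every", "some", "any", "no", "both", "all", "another", "such")
.lex$pron_poss <- c("my", "your", "his", "its", "our", "their", "her")
.lex$pron <- c("i", "you", "he", "she", "it", "we", "they", "me", "him",
  "us", "them", "mine", "yours", "hers", "ours", "theirs", "myself",
  "yourself", "himself", "herself", "itself", "ourselves", "themselves",
  "who", "whom", "whose", "what", "which", "someone", "anyone", "everyone",
  "nothing", "something", "anything", "everything")
.lex$rel_pron <- c("who", "whom", "whose", "which", "that")
.lex$adp <- c("in", "on", "at", "by", "for", "with", "from", "of", "to",
  "about", "under", "over", "between", "through", "during", "against",
  "into", "onto", "across", "behind", "beside", "near", "without", "within",
  "among", "around", "upon", "toward", "towards", "after", "before")
.lex$aux_be <- c("be", "am", "is", "are", "was", "were", "been", "being")
.lex$aux_have <- c("have", "has", "had", "having")
.lex$aux_do <- c("do", "does", "did")
.lex$modal <- c("will", "would", "can", "could", "shall", "should", "may",
  "might", "must")
.lex$cconj <- c("and", "or", "but", "nor", "yet")
.lex$sconj <- c("because", "although", "though", "if", "while", "when",
  "unless", "since", "whereas", "whether", "until")
.lex$intj <- c("oh", "yes", "yeah", "wow", "hmm", "ah", "hello", "hi",
  "um", "uh", "okay", "ok", "alas", "oops", "hey", "please")
.lex$part <- c("not", "'s", "’s", "n't", "'t", "’t")
.lex$adv <- c("always", "often", "never", "very", "too", "also", "then",
  "here", "there", "now", "well", "quite", "rather", "really", "sometimes",
  "usually", "again", "soon", "today", "yesterday", "tomorrow", "almost",
  "already", "just", "still", "even", "once", "twice", "together", "away",
  "back", "however", "perhaps", "maybe")
.lex$adj <- c("old", "good", "bad", "big", "small", "sunny", "rainy", "happy",
  "sad", "red", "blue", "green", "black", "white", "new", "little", "nice",
  "warm", "cold", "young", "long", "short", "high", "low", "easy", "hard",
  "simple", "large", "great", "tall", "fast", "slow", "bright", "dark",
  "early", "late", "full", "empty", "clean", "dirty", "quiet", "loud",
  "strong", "weak", "rich", "poor", "free", "busy", "soft", "heavy",
  "light", "same", "different", "important", "possible", "ready", "tired",
  "whole", "main", "fine", "clear", "deep", "wide", "safe", "proud")
# irregular verbs: past / past-participle -> base
.lex$irregular_verb <- c(
  sat = "sit", ran = "run", fell = "fall", fallen = "fall", threw = "throw",
  thrown = "throw", went = "go", gone = "go", gave = "give", given = "give",
  took = "take", taken = "take", saw = "see", seen = "see", came = "come",
  said = "say", made = "make", knew = "know", known = "know", got = "get",
  gotten = "get", found = "find", left = "leave", told = "tell", felt = "feel",
  kept = "keep", began = "begin", begun = "begin", brought = "bring",
  wrote = "write", written = "write", stood = "stand", heard = "hear",
  meant = "mean", met = "meet", paid = "pay", sent = "send", set = "set",
  sold = "sell", spoke = "speak", spoken = "speak", spent = "spend",
  taught = "teach", thought = "think", understood = "understand",
  won = "win", sang = "sing", sung = "sing", drank = "drink", drunk = "drink",
  ate = "eat", eaten = "eat", slept = "sleep", broke = "break",
  broken = "break", built = "build", caught = "catch", chose = "choose",
  chosen = "choose", drew = "draw", drawn = "draw", drove = "drive",
  driven = "drive", flew = "fly", flown = "fly", forgot = "forget",
  grew = "grow", grown = "grow", held = "hold", lost = "lose", rose = "rise",
  risen = "rise", saccording = "accord", put = "put", read = "read",
  let = "let", hit = "hit", cut = "cut", hurt = "hurt", shut = "shut",
  woke = "wake", wore = "wear", worn = "wear", swam = "swim", swum = "swim")
.lex$verb_base <- c("run", "sit", "see", "sleep", "eat", "go", "throw",
  "fall", "purr", "decorate", "convert", "assess", "jump", "walk", "talk",
  "play", "like", "love", "want", "need", "make", "take", "give", "know",
  "think", "say", "tell", "find", "use", "work", "call", "try", "ask",
  "feel", "leave", "put", "mean", "keep", "let", "begin", "help", "show",
  "hear", "turn", "start", "bring", "write", "stand", "lose", "pay", "meet",
  "include", "continue", "learn", "change", "lead", "watch", "follow",
  "stop", "create", "speak", "read", "spend", "grow", "open", "win",
  "teach", "offer", "remember", "consider", "appear", "buy", "serve",
  "send", "build", "stay", "reach", "remain", "live", "move", "look",
  "come", "bark", "chase", "carry", "hold", "wait", "sing", "drink",
  "catch", "wash", "cook", "clean", "fix", "visit", "rest", "smile",
  "laugh", "cry", "dance", "drive", "fly", "rain", "snow", "shine",
  "greet", "thank", "describe", "paint", "draw")
# verbs whose -ed / -ing stem needs a restored final e
.lex$e_restore <- c("decorat", "creat", "describ", "includ", "continu",
  "us", "lov", "lik", "chas", "mov", "liv", "danc", "driv", "smil",
  "serv", "chang")
.lex$noun <- c("cat", "dog", "house", "friend", "ball", "mat", "weather",
  "bedroom", "professor", "student", "assignment", "rain", "sun", "book",
  "table", "chair", "garden", "tree", "bird", "fish", "water", "milk",
  "bread", "door", "window", "room", "school", "teacher", "doctor", "nurse",
  "child", "children", "man", "woman", "men", "women", "people", "person",
  "king", "queen", "city", "town", "road", "car", "bus", "train", "boat",
  "river", "mountain", "flower", "grass", "sky", "cloud", "star", "moon",
  "day", "night", "morning", "evening", "week", "year", "time", "hour",
  "hand", "head", "eye", "ear", "mouth", "foot", "leg", "arm", "heart",
  "mind", "word", "sentence", "story", "letter", "paper", "pen", "pencil",
  "music", "song", "game", "toy", "food", "apple", "orange", "egg",
  "cheese", "soup", "tea", "coffee", "cup", "plate", "spoon", "knife",
  "fork", "box", "bag", "hat", "coat", "shoe", "shirt", "dress", "bed",
  "kitchen", "bathroom", "floor", "wall", "roof", "yard", "fence", "gate",
  "park", "shop", "store", "market", "street", "bridge", "field", "farm",
  "horse", "cow", "sheep", "pig", "chicken", "duck", "mouse", "rabbit",
  "lion", "tiger", "bear", "fox", "wolf", "snake", "frog", "bee", "ant")
.lex$person <- c("john", "mary", "alice", "bob", "napoleon", "anna", "peter",
  "james", "sarah", "emma", "david", "michael", "laura", "tom", "lucy",
  "george", "helen", "paul", "jane", "mark", "iris", "agatha", "ronald")
.lex$place <- c("france", "paris", "london", "oslo", "norway", "rome",
  "italy", "berlin", "germany", "madrid", "spain", "athens", "greece",
  "amsterdam", "lisbon", "vienna", "europe", "america", "england")
.lex$org <- c("unicef", "google", "microsoft", "nasa", "unesco", "who")

# ---- tagging ---------------------------------------------------------------

.pos_display_map <- c(
  NOUN = "Noun", PROPN = "Proper Noun", VERB = "Verb", AUX = "Auxiliary",
  ADJ = "Adjective", ADV = "Adverb", PRON = "Pronoun", DET = "Determiner",
  ADP = "Adposition", CCONJ = "Coordinating Conjunction",
  SCONJ = "Subordinating Conjunction", PART = "Particle",
  INTJ = "Interjection", NUM = "Numeral", PUNCT = "Punctuation",
  SYM = "Symbol", X = "Other"
)

#' Human-readable part-of-speech name
#' @param pos universal POS code (e.g. "NOUN").
#' @return display name (e.g. "Noun").
#' @export
pos_display <- function(pos) {
  out <- .pos_display_map[pos]
  out[is.na(out)] <- pos[is.na(out)]
  unname(out)
}

.dep_display_map <- c(
  root = "Root", nsubj = "Nominal Subject",
  nsubjpass = "Nominal Subject (Passive)", aux = "Auxiliary",
  auxpass = "Auxiliary (Passive)", cop = "Copula", det = "Determiner",
  poss = "Possession Modifier", case = "Case Marking",
  amod = "Adjectival Modifier", advmod = "Adverbial Modifier",
  dobj = "Direct Object", prep = "Prepositional Modifier",
  pobj = "Object of Preposition", mark = "Marker",
  advcl = "Adverbial Clause Modifier", relcl = "Relative Clause Modifier",
  ccomp = "Clausal Complement", xcomp = "Open Clausal Complement",
  conj = "Conjunct", cc = "Coordinating Conjunction", intj = "Interjection",
  punct = "Punctuation", parataxis = "Parataxis", compound = "Compound",
  attr = "Attribute", neg = "Negation Modifier", nummod = "Numeric Modifier",
  dep = "Unclassified Dependent"
)

#' Human-readable dependency-relation name
#' @param dep dependency code (e.g. "nsubjpass").
#' @return display name (e.g. "Nominal Subject (Passive)").
#' @export
dep_display <- function(dep) {
  out <- .dep_display_map[dep]
  out[is.na(out)] <- dep[is.na(out)]
  unname(out)
}

# initial context-free tag for one lowercased word token
.tag_word <- function(lower, surface, first_in_sentence) {
  if (grepl("^[0-9]", lower)) return(c("NUM", "Cardinal Number", lower))
  if (lower %in% .lex$part) {
    detail <- if (lower %in% c("'s", "’s")) "Possessive Ending" else "Particle"
    lemma <- if (lower %in% c("n't", "'t", "’t")) "not" else
      if (lower %in% c("'s", "’s")) "'s" else lower
    return(c("PART", detail, lemma))
  }
  if (lower %in% .lex$aux_be) return(c("AUX", .verb_detail(lower), "be"))
  if (lower %in% .lex$aux_have) return(c("AUX", .verb_detail(lower), "have"))
  if (lower %in% .lex$aux_do) return(c("AUX", .verb_detail(lower), "do"))
  if (lower %in% .lex$modal) return(c("AUX", "Verb, Modal", lower))
  if (lower %in% .lex$det) return(c("DET", "Determiner", lower))
  if (lower %in% .lex$pron_poss) return(c("PRON", "Pronoun, Possessive", lower))
  if (lower %in% .lex$pron) return(c("PRON", "Pronoun, Personal", lower))
  if (lower %in% .lex$cconj) return(c("CCONJ", "Conjunction, Coordinating", lower))
  if (lower %in% .lex$sconj) return(c("SCONJ", "Conjunction, Subordinating", lower))
  if (lower %in% .lex$adp) return(c("ADP", "Adposition", lower))
  if (lower %in% .lex$intj) return(c("INTJ", "Interjection", lower))
  if (lower %in% .lex$adv) return(c("ADV", "Adverb", lower))
  if (lower %in% .lex$adj) return(c("ADJ", "Adjective", lower))
  if (lower %in% names(.lex$irregular_verb)) {
    base <- unname(.lex$irregular_verb[lower])
    detail <- if (lower %in% c("fallen", "thrown", "given", "taken", "seen",
      "known", "gotten", "written", "spoken", "eaten", "broken", "chosen",
      "drawn", "driven", "flown", "grown", "risen", "sung", "swum", "drunk",
      "begun", "worn")) "Verb, Past Participle" else "Verb, Past Tense"
    return(c("VERB", detail, base))
  }
  if (lower %in% .lex$verb_base) return(c("VERB", "Verb, Base Form", lower))
  if (lower %in% .lex$noun) {
    return(c("NOUN", "Noun, Singular or Mass", lower))
  }
  # proper noun: capitalized, either non-sentence-initial or in gazetteer
  gaz <- lower %in% c(.lex$person, .lex$place, .lex$org)
  if (grepl("^\\p{Lu}", surface, perl = TRUE) && (gaz || !first_in_sentence)) {
    return(c("PROPN", "Noun, Proper Singular", lower))
  }
  # suffix heuristics
  if (grepl("ly$", lower) && nchar(lower) > 3) return(c("ADV", "Adverb", lower))
  if (grepl("(ous|ful|ive|ish|able|ible|ic|al)$", lower) && nchar(lower) > 4) {
    return(c("ADJ", "Adjective", lower))
  }
  if (grepl("ing$", lower) && nchar(lower) > 4) {
    return(c("VERB", "Verb, Gerund or Present Participle", .strip_ing(lower)))
  }
  if (grepl("ed$", lower) && nchar(lower) > 3) {
    return(c("VERB", "Verb, Past Participle", .strip_ed(lower)))
  }
  if (grepl("(tion|sion|ment|ness|ity|ance|ence|ship|hood)s?$", lower)) {
    return(c("NOUN", .noun_detail(lower), .noun_lemma(lower)))
  }
  if (grepl("[^su]s$", lower) && nchar(lower) > 2) {
    return(c("NOUN", "Noun, Plural", .noun_lemma(lower)))
  }
  c("NOUN", "Noun, Singular or Mass", lower)
}

.verb_detail <- function(lower) {
  switch(lower,
    is = , has = , does = "Verb, 3Rd Person Singular Present",
    was = , were = , had = , did = "Verb, Past Tense",
    been = "Verb, Past Participle",
    being = , having = "Verb, Gerund or Present Participle",
    "Verb, Non-3Rd Person Singular Present"
  )
}

.noun_detail <- function(lower) {
  if (grepl("[^s]s$", lower)) "Noun, Plural" else "Noun, Singular or Mass"
}

.noun_lemma <- function(lower) {
  if (grepl("ies$", lower)) return(sub("ies$", "y", lower))
  if (grepl("(ses|xes|zes|ches|shes)$", lower)) return(sub("es$", "", lower))
  if (grepl("[^su]s$", lower)) return(sub("s$", "", lower))
  lower
}

.strip_ed <- function(lower) {
  stem <- sub("ed$", "", lower)
  if (grepl("i$", stem)) return(sub("i$", "y", stem))
  if (nchar(stem) > 2 && substr(stem, nchar(stem), nchar(stem)) ==
      substr(stem, nchar(stem) - 1L, nchar(stem) - 1L) &&
      !grepl("(ss|ll|ff|zz)$", stem)) {
    return(substr(stem, 1L, nchar(stem) - 1L))
  }
  if (stem %in% .lex$e_restore || paste0(stem, "e") %in% .lex$verb_base) {
    return(paste0(stem, "e"))
  }
  stem
}

.strip_ing <- function(lower) {
  stem <- sub("ing$", "", lower)
  if (nchar(stem) > 2 && substr(stem, nchar(stem), nchar(stem)) ==
      substr(stem, nchar(stem) - 1L, nchar(stem) - 1L) &&
      !grepl("(ss|ll|ff|zz)$", stem)) {
    return(substr(stem, 1L, nchar(stem) - 1L))
  }
  if (stem %in% .lex$e_restore || paste0(stem, "e") %in% .lex$verb_base) {
    return(paste0(stem, "e"))
  }
  stem
}

# verb 3sg: "sees", "sleeps" start out tagged as plural nouns; inside a
# sentence that otherwise lacks a verb, retag the first candidate after the
# subject head. Candidate = s-form whose stem (or stem+e) is a known verb, or
# any s-form if the sentence would otherwise be verbless.
.retag_3sg <- function(pos, lower, detail, lemma) {
  has_verb <- any(pos %in% c("VERB"))
  if (has_verb) return(list(pos = pos, detail = detail, lemma = lemma))
  n <- length(pos)
  first_noun <- match(TRUE, pos %in% c("NOUN", "PROPN", "PRON"))
  if (is.na(first_noun) || first_noun == n) {
    return(list(pos = pos, detail = detail, lemma = lemma))
  }
  for (i in (first_noun + 1L):n) {
    if (pos[i] == "NOUN" && grepl("[^s]s$", lower[i])) {
      stem <- .sform_stem(lower[i])
      pos[i] <- "VERB"
      detail[i] <- "Verb, 3Rd Person Singular Present"
      lemma[i] <- stem
      break
    }
  }
  list(pos = pos, detail = detail, lemma = lemma)
}

.sform_stem <- function(lower) {
  if (grepl("ies$", lower)) return(sub("ies$", "y", lower))
  if (grepl("(ses|xes|zes|ches|shes)$", lower)) {
    stem <- sub("es$", "", lower)
    return(stem)
  }
  stem <- sub("s$", "", lower)
  if (grepl("ee$", stem)) return(stem)
  if (!stem %in% .lex$verb_base && paste0(stem, "e") %in% .lex$verb_base) {
    return(paste0(stem, "e"))
  }
  stem
}

# ---- dependency pass (per sentence) ----------------------------------------

# assigns dep + head (absolute 1-based indices; root points to itself)
.parse_sentence <- function(pos, lower, detail, idx) {
  n <- length(pos)
  dep <- rep("dep", n)
  head <- rep(NA_integer_, n)
  is_verb <- pos == "VERB"
  is_aux <- pos == "AUX"
  is_nom <- pos %in% c("NOUN", "PROPN", "PRON", "NUM")
  is_punct <- pos %in% c("PUNCT", "SYM") | !grepl("[\\p{L}0-9]", lower, perl = TRUE)

  # passive: a form of "be" followed (allowing adverbs) by a past participle
  passive_verb <- integer(0)
  auxpass_of <- rep(NA_integer_, n)
  for (i in which(is_aux & lower %in% .lex$aux_be)) {
    j <- i + 1L
    while (j <= n && pos[j] == "ADV") j <- j + 1L
    if (j <= n && is_verb[j] && grepl("Past Participle", detail[j])) {
      passive_verb <- c(passive_verb, j)
      auxpass_of[i] <- j
    }
  }

  # root: first passive verb, else first main verb, else copular predicate,
  # else first nominal, else first non-punct token
  root <- if (length(passive_verb)) passive_verb[1L] else
    if (any(is_verb)) which(is_verb)[1L] else NA_integer_
  cop_pred <- NA_integer_
  if (is.na(root) && any(is_aux)) {
    a <- which(is_aux)[1L]
    k <- a + 1L
    while (k <= n && pos[k] %in% c("ADV", "DET")) k <- k + 1L
    if (k <= n && pos[k] %in% c("ADJ", "NOUN", "PROPN", "NUM", "PRON")) {
      root <- k
      cop_pred <- a
    } else {
      root <- a
    }
  }
  if (is.na(root)) {
    # verbless fragment: prefer a nominal or adjectival head
    root <- match(TRUE, pos %in% c("NOUN", "PROPN", "PRON", "ADJ", "NUM"))
    if (is.na(root)) root <- match(TRUE, !is_punct)
    if (is.na(root)) root <- 1L
  }
  dep[root] <- "root"
  head[root] <- root
  if (!is.na(cop_pred)) {
    dep[cop_pred] <- "cop"
    head[cop_pred] <- root
  }

  # clause heads: further finite verbs become conj / advcl / relcl / parataxis
  verb_heads <- root
  for (v in setdiff(which(is_verb), root)) {
    if (!is.na(head[v])) next
    # participle directly after its auxiliary chain belongs to that verb group
    prev_cc <- rev(which(pos[seq_len(v - 1L)] == "CCONJ"))
    prev_sconj <- rev(which(pos[seq_len(v - 1L)] == "SCONJ"))
    prev_rel <- rev(which(lower[seq_len(v - 1L)] %in% .lex$rel_pron &
        pos[seq_len(v - 1L)] == "PRON"))
    between_punct <- function(a) any(is_punct[seq(a, v)])
    if (length(prev_sconj) && !between_punct(prev_sconj[1L])) {
      dep[v] <- "advcl"; head[v] <- root
    } else if (length(prev_rel) && !between_punct(prev_rel[1L]) &&
        prev_rel[1L] > 1L && is_nom[prev_rel[1L] - 1L]) {
      dep[v] <- "relcl"; head[v] <- prev_rel[1L] - 1L
    } else if (length(prev_cc) && !between_punct(prev_cc[1L])) {
      dep[v] <- "conj"; head[v] <- root
    } else {
      dep[v] <- "parataxis"; head[v] <- root
    }
    verb_heads <- c(verb_heads, v)
  }
  nearest_verb <- function(i) {
    if (!length(verb_heads)) return(root)
    verb_heads[which.min(abs(verb_heads - i))]
  }

  # auxiliaries
  for (i in which(is_aux)) {
    if (!is.na(head[i])) next
    if (!is.na(auxpass_of[i])) {
      dep[i] <- "auxpass"; head[i] <- auxpass_of[i]
    } else {
      # attach to next verb if any, else to root
      nv <- which(is_verb & seq_len(n) > i)
      dep[i] <- "aux"
      head[i] <- if (length(nv)) nv[1L] else root
      if (i == root) { dep[i] <- "root"; head[i] <- i }
    }
  }

  # possessives: PRON-poss or NOUN followed by possessive 's attach to the
  # next nominal; the clitic marks case on the possessor
  for (i in seq_len(n)) {
    if (!is.na(head[i])) next
    if (pos[i] == "PRON" && detail[i] == "Pronoun, Possessive" && i < n) {
      nn <- which(is_nom & seq_len(n) > i)
      if (length(nn)) { dep[i] <- "poss"; head[i] <- nn[1L]; next }
    }
    if (pos[i] == "PART" && lower[i] %in% c("'s", "’s") && i > 1L) {
      dep[i] <- "case"; head[i] <- i - 1L
      if (is_nom[i - 1L] && is.na(head[i - 1L])) {
        nn <- which(is_nom & seq_len(n) > i)
        if (length(nn)) { dep[i - 1L] <- "poss"; head[i - 1L] <- nn[1L] }
      }
      next
    }
  }

  # prepositions and their objects
  for (i in which(pos == "ADP")) {
    if (!is.na(head[i])) next
    pv <- verb_heads[verb_heads < i]
    dep[i] <- "prep"
    head[i] <- if (length(pv)) pv[length(pv)] else root
    nn <- which(is_nom & seq_len(n) > i & is.na(head))
    if (length(nn)) { dep[nn[1L]] <- "pobj"; head[nn[1L]] <- i }
  }

  # subjects: last unattached nominal before each verb head
  for (v in verb_heads) {
    cand <- which(is_nom & seq_len(n) < v & is.na(head))
    if (length(cand)) {
      s <- cand[length(cand)]
      dep[s] <- if (v %in% passive_verb) "nsubjpass" else "nsubj"
      head[s] <- v
    }
  }
  if (!is.na(cop_pred) && is.na(head[1L])) {
    # copular clause: subject of the predicate root
    cand <- which(is_nom & seq_len(n) < root & is.na(head))
    if (length(cand)) {
      s <- cand[length(cand)]
      dep[s] <- "nsubj"; head[s] <- root
    }
  }

  # objects: first unattached nominal after a verb head, no ADP in between
  for (v in verb_heads) {
    nn <- which(is_nom & seq_len(n) > v & is.na(head))
    for (o in nn) {
      if (any(pos[seq(v, o)] == "ADP")) break
      dep[o] <- "dobj"; head[o] <- v
      break
    }
  }

  # remaining modifiers
  for (i in seq_len(n)) {
    if (!is.na(head[i])) next
    p <- pos[i]
    if (p == "DET") {
      nn <- which(is_nom & seq_len(n) > i)
      dep[i] <- "det"; head[i] <- if (length(nn)) nn[1L] else root
    } else if (p == "ADJ") {
      nn <- which(is_nom & seq_len(n) > i)
      if (length(nn)) { dep[i] <- "amod"; head[i] <- nn[1L] }
      else { dep[i] <- "advmod"; head[i] <- root }
    } else if (p == "ADV") {
      dep[i] <- "advmod"; head[i] <- nearest_verb(i)
      if (pos[root] %in% c("ADJ", "NOUN") && !any(is_verb)) head[i] <- root
    } else if (p == "PART") {
      dep[i] <- if (lower[i] %in% c("not", "n't", "'t", "’t")) "neg" else "prt"
      head[i] <- nearest_verb(i)
    } else if (p == "SCONJ") {
      vv <- which(is_verb & seq_len(n) > i)
      dep[i] <- "mark"; head[i] <- if (length(vv)) vv[1L] else root
    } else if (p == "CCONJ") {
      dep[i] <- "cc"; head[i] <- root
    } else if (p == "INTJ") {
      dep[i] <- "intj"; head[i] <- root
    } else if (p == "NUM") {
      nn <- which(is_nom & seq_len(n) > i)
      dep[i] <- "nummod"; head[i] <- if (length(nn)) nn[1L] else root
    } else if (is_punct[i]) {
      dep[i] <- "punct"; head[i] <- root
    } else if (is_nom[i]) {
      # leftover nominal: noun-noun compound to a following nominal, else attr
      nn <- which(is_nom & seq_len(n) > i & !is.na(head))
      if (length(nn)) { dep[i] <- "compound"; head[i] <- nn[1L] }
      else { dep[i] <- "attr"; head[i] <- root }
    } else {
      dep[i] <- "dep"; head[i] <- root
    }
  }
  # negation particles mislabelled above
  neg <- which(lower %in% c("not", "n't", "'t") & dep != "root")
  dep[neg] <- "neg"
  list(dep = dep, head = idx[head])
}

# ---- entities --------------------------------------------------------------

.entity_label <- function(pos, lower, surface) {
  n <- length(pos)
  ent <- rep(NA_character_, n)
  ent[lower %in% .lex$person] <- "Person"
  ent[lower %in% .lex$place] <- "Place"
  ent[lower %in% .lex$org] <- "Organization"
  ent[pos == "NUM"] <- "Quantity"
  unknown_propn <- pos == "PROPN" & is.na(ent)
  ent[unknown_propn] <- "Person"
  ent
}

# ---- the backend object ----------------------------------------------------

.rule_en_annotate <- function(tokens, sentences, language, precision) {
  n <- nrow(tokens)
  lower <- tolower(tokens$surface)
  pos <- character(n); detail <- character(n); lemma <- character(n)
  sent_of <- tokens$sentence
  first_tok <- !duplicated(sent_of)
  for (i in seq_len(n)) {
    if (!tokens$is_word[i]) {
      pos[i] <- "PUNCT"; detail[i] <- "Punctuation"; lemma[i] <- lower[i]
    } else {
      # sentence-initial = first *word* token of its sentence
      fi <- i == match(sent_of[i], sent_of) ||
        all(!tokens$is_word[seq(match(sent_of[i], sent_of), i - 1L)])
      tag <- .tag_word(lower[i], tokens$surface[i], fi)
      pos[i] <- tag[1L]; detail[i] <- tag[2L]; lemma[i] <- tag[3L]
    }
  }
  # noun/verb ambiguity: a base-form "verb" right after a determiner or
  # possessive is a nominal ("the rain", "my run")
  for (i in which(pos == "VERB" & detail == "Verb, Base Form")) {
    if (i > 1L && (pos[i - 1L] %in% c("DET", "ADJ") ||
        detail[i - 1L] == "Pronoun, Possessive")) {
      pos[i] <- "NOUN"; detail[i] <- "Noun, Singular or Mass"
    }
  }
  dep <- character(n); head <- integer(n)
  for (s in seq_len(nrow(sentences))) {
    idx <- seq(sentences$start[s], sentences$end[s])
    rt <- .retag_3sg(pos[idx], lower[idx], detail[idx], lemma[idx])
    pos[idx] <- rt$pos; detail[idx] <- rt$detail; lemma[idx] <- rt$lemma
    pr <- .parse_sentence(pos[idx], lower[idx], detail[idx], idx)
    dep[idx] <- pr$dep; head[idx] <- pr$head
  }
  tokens$lower <- lower
  tokens$lemma <- lemma
  tokens$pos <- pos
  tokens$pos_detail <- detail
  tokens$dep <- dep
  tokens$head <- head
  tokens$entity <- .entity_label(pos, lower, tokens$surface)
  tokens
}

rule_en_backend <- list(
  name = "rule_en",
  languages = "en",
  annotate = .rule_en_annotate
)
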