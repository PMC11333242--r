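# Independent oracles used across the suite. These are deliberately written
# as naive, direct translations of the published formulas and of the textbook
# edit-distance recurrence, sharing no code with the package internals.

# ---- readability formulas, hand-coded --------------------------------------

oracle_fre <- function(w, s, y) 206.835 - 1.015 * w / s - 84.6 * y / w
oracle_fkg <- function(w, s, y) 0.39 * w / s + 11.8 * y / w - 15.59
oracle_fog <- function(w, s, cx) 0.4 * (w / s + 100 * cx / w)
oracle_cli <- function(w, s, l) {
  0.0588 * (l / w * 100) - 0.296 * (s / w * 100) - 15.8
}
oracle_ari <- function(w, s, ch) 4.71 * ch / w + 0.5 * w / s
oracle_smog <- function(s, poly) 1.0430 * sqrt(poly * 30 / s) + 3.1291
oracle_dale_chall <- function(w, s, diff) {
  raw <- 0.1579 * (diff / w * 100) + 0.0496 * (w / s)
  adj <- if (diff / w > 0.05) raw + 3.6365 else raw
  c(raw = raw, adjusted = adj)
}
oracle_linsear <- function(easy, hard, sentences) {
  r <- (easy + 3 * hard) / sentences
  if (r > 20) r / 2 else r / 2 - 1
}

# ---- diversity measures, hand-coded ----------------------------------------

oracle_diversity <- function(tokens, segment_size = 100L) {
  N <- length(tokens)
  V <- length(unique(tokens))
  seg_ttrs <- c()
  k <- 1L
  while (k + segment_size - 1L <= N) {
    seg <- tokens[k:(k + segment_size - 1L)]
    seg_ttrs <- c(seg_ttrs, length(unique(seg)) / segment_size)
    k <- k + segment_size
  }
  list(
    ttr = V / N * 100,
    cttr = V / sqrt(2 * N),
    maas = if (V > exp(1) && N > exp(1)) log(log(V)) / log(log(N)) else NA_real_,
    msttr = if (length(seg_ttrs)) mean(seg_ttrs) else NA_real_,
    herdan_c = if (N > 1) log(V) / log(N) else NA_real_
  )
}

# ---- restricted Damerau-Levenshtein: brute-force dynamic program -----------
# Plain memoized recursion on suffixes; also enumerates every minimal-cost
# error-type decomposition, so the package's deterministic backtrace can be
# checked for membership rather than for one arbitrary tie-break.

osa_oracle <- function(a, b) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  dist_memo <- new.env(parent = emptyenv())
  dist <- function(i, j) {
    key <- paste(i, j)
    hit <- dist_memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i > n && j > m) 0L
    else {
      cands <- c()
      if (i <= n) cands <- c(cands, dist(i + 1L, j) + 1L)
      if (j <= m) cands <- c(cands, dist(i, j + 1L) + 1L)
      if (i <= n && j <= m) {
        cands <- c(cands, dist(i + 1L, j + 1L) + as.integer(a[i] != b[j]))
      }
      if (i + 1L <= n && j + 1L <= m && a[i] == b[j + 1L] && a[i + 1L] == b[j]) {
        cands <- c(cands, dist(i + 2L, j + 2L) + 1L)
      }
      min(cands)
    }
    dist_memo[[key]] <- val
    val
  }
  dec_memo <- new.env(parent = emptyenv())
  # decomposition vectors (ins, del, sub, trans) of all minimal scripts
  decomps <- function(i, j) {
    key <- paste(i, j)
    hit <- dec_memo[[key]]
    if (!is.null(hit)) return(hit)
    here <- dist(i, j)
    out <- list()
    if (i > n && j > m) {
      out <- list(c(0L, 0L, 0L, 0L))
    } else {
      if (i <= n && j <= m && a[i] == b[j] && dist(i + 1L, j + 1L) == here) {
        out <- c(out, decomps(i + 1L, j + 1L))
      }
      if (i <= n && j <= m && a[i] != b[j] &&
          dist(i + 1L, j + 1L) + 1L == here) {
        out <- c(out, lapply(decomps(i + 1L, j + 1L),
          function(v) v + c(0L, 0L, 1L, 0L)))
      }
      if (i + 1L <= n && j + 1L <= m && a[i] == b[j + 1L] &&
          a[i + 1L] == b[j] && dist(i + 2L, j + 2L) + 1L == here) {
        out <- c(out, lapply(decomps(i + 2L, j + 2L),
          function(v) v + c(0L, 0L, 0L, 1L)))
      }
      if (i <= n && dist(i + 1L, j) + 1L == here) {
        out <- c(out, lapply(decomps(i + 1L, j),
          function(v) v + c(0L, 1L, 0L, 0L)))
      }
      if (j <= m && dist(i, j + 1L) + 1L == here) {
        out <- c(out, lapply(decomps(i, j + 1L),
          function(v) v + c(1L, 0L, 0L, 0L)))
      }
      out <- unique(out)
    }
    dec_memo[[key]] <- out
    out
  }
  list(distance = dist(1L, 1L), decompositions = decomps(1L, 1L))
}

# all strings of lengths 0..max_len over an alphabet
all_strings <- function(alphabet, max_len) {
  out <- ""
  level <- ""
  for (l in seq_len(max_len)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}
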