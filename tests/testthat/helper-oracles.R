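# Independent oracles, deliberately coded from first principles and not
# through the package's internal grid/alignment machinery.

# semitone map restated locally
ORACLE_SEMITONES <- c(D = 0, R = 2, M = 4, F = 5, S = 7, L = 9, T = 11)

# slot-level pitch expansion of a voice_score, via plain string parsing
oracle_slots <- function(score) {
  out <- c()
  for (i in seq_len(nrow(score$bars))) {
    letters_i <- strsplit(score$bars$formula[i], "")[[1]]
    durs_i <- as.numeric(strsplit(score$bars$durations[i], ",")[[1]])
    for (k in seq_along(letters_i)) {
      out <- c(out, rep(ORACLE_SEMITONES[[letters_i[k]]], 2 * durs_i[k]))
    }
  }
  out
}

# consonant fraction of two voices at a bar offset (bar i of A vs i+off of B)
oracle_f_cons <- function(vA, vB, off) {
  a <- oracle_slots(vA)
  b <- oracle_slots(vB)
  nA <- length(a) / 6
  nB <- length(b) / 6
  lo <- max(0, -off)
  hi <- min(nA - 1, nB - 1 - off)
  if (hi < lo) return(NA_real_)
  tot <- 0L
  hit <- 0L
  for (bar in lo:hi) {
    for (s in 1:6) {
      pa <- a[bar * 6 + s]
      pb <- b[(bar + off) * 6 + s]
      d <- abs(pa - pb) %% 12
      tot <- tot + 1L
      if (d %in% c(0, 5, 7)) hit <- hit + 1L
    }
  }
  hit / tot
}

# exhaustive best-offset scan with the spec tie-break (small |offset| first,
# negative before positive)
oracle_best_offset <- function(vA, vB, max_offset) {
  offs <- (-max_offset):max_offset
  offs <- offs[order(abs(offs), offs)]
  best_off <- NA_integer_
  best_f <- -Inf
  for (o in offs) {
    f <- oracle_f_cons(vA, vB, o)
    if (!is.na(f) && f > best_f + 1e-12) {
      best_f <- f
      best_off <- o
    }
  }
  list(offset = best_off, f_cons = best_f)
}

# brute-force global affine-gap alignment score by full path enumeration
# (no dynamic programming); gap of length L costs open + L * ext
oracle_align_score <- function(a, b, submat, open = 10, ext = 0.5) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  n <- length(sa)
  m <- length(sb)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, submat[sa[i], sb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- if (identical(prev, "X")) ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- if (identical(prev, "Y")) ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "start")
}

# BLOSUM62 as the tests' shared default matrix
oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# single-note bars from arbitrary degree letters (for degree-level fixtures)
degrees_voice <- function(letters_vec, label = "deg") {
  voice_score(data.frame(bar_index = seq_along(letters_vec) - 1L,
                         codon = "UGC", formula = letters_vec,
                         durations = "3", stringsAsFactors = FALSE),
              label = label)
}
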