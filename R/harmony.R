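# Polyphonic comparison of sonified voices.
#
# Voices are compared on an eighth-note grid: every 3/4 bar contributes six
# slots of half a beat, and a note of duration d beats sounds in 2*d
# consecutive slots. Slot-level comparison keeps voices with different
# rhythms comparable; a bar counts as a unison bar only when all six of its
# slot pairs are unisons.

.SLOTS_PER_BAR <- 6L

# per-bar slot expansion of degree letters; returns character matrix-free list
.bar_slots <- function(formula, durations) {
  ltrs <- strsplit(formula, "")
  durs <- lapply(strsplit(durations, ",", fixed = TRUE), as.numeric)
  mapply(function(l, d) rep(l, times = as.integer(round(2 * d))),
         ltrs, durs, SIMPLIFY = FALSE)
}

#' Sample a score on the eighth-note grid
#'
#' @param score a [voice_score].
#' @return Character vector of degree letters, length `6 * n_bars(score)`;
#'   sustained notes fill their slots.
#' @examples
#' sample_grid(sonify("GGA"))  # "S" "S" "S" "S" "L" "L"
#' @export
sample_grid <- function(score) {
  stopifnot(inherits(score, "voice_score"))
  if (nrow(score$bars) == 0L) return(character(0))
  out <- unlist(.bar_slots(score$bars$formula, score$bars$durations),
                use.names = FALSE)
  stopifnot(length(out) == .SLOTS_PER_BAR * nrow(score$bars))
  out
}

# integer semitone grid (fast path used throughout)
.grid_semitones <- function(score) {
  unname(.SOLFEGE_SEMITONES[sample_grid(score)])
}

#' Classify an interval between two pitches
#'
#' Intervals are measured in semitones of the fixed single-octave
#' realization, reduced mod 12 and classified as `unison` (0), `P4` (5),
#' `P5` (7) or `other`. Classification is symmetric in the two pitches;
#' the tritone counts as `other`.
#'
#' @param a,b integer semitone offsets (vectors recycle).
#' @return Character vector of labels.
#' @export
interval_class <- function(a, b) {
  d <- abs(a - b) %% 12L
  ifelse(d == 0L, "unison", ifelse(d == 5L, "P4", ifelse(d == 7L, "P5", "other")))
}

#' Consonance profile of two voices at a fixed bar offset
#'
#' Aligns bar `i` of `vA` with bar `i + offset_bars` of `vB` (gapless integer
#' bar offsets only) and classifies every overlapping eighth-note slot pair.
#' `f_unison`, `f_p45` and `f_cons = f_unison + f_p45` are fractions of
#' overlapping slots.
#'
#' @param vA,vB [voice_score] objects.
#' @param offset_bars integer; positive values slide `vB` earlier relative to
#'   `vA` (bar i of A meets bar i + offset of B).
#' @return A `consonance_profile`: list with `offset_bars`, `overlap_bars`,
#'   `bar_counts` (per-bar slot counts of each interval class, rows indexed
#'   by `bar_a`, the 0-based bar in `vA`), `f_unison`, `f_p45`, `f_cons`.
#' @examples
#' v <- sonify(random_cds(20, seed = 1))
#' consonance_profile(v, v, 0)$f_unison  # 1
#' @export
consonance_profile <- function(vA, vB, offset_bars = 0L) {
  stopifnot(inherits(vA, "voice_score"), inherits(vB, "voice_score"))
  offset_bars <- as.integer(offset_bars)
  nA <- n_bars(vA); nB <- n_bars(vB)
  # bars i of A (0-based) align with bars i + offset of B
  lo <- max(0L, -offset_bars)
  hi <- min(nA - 1L, nB - 1L - offset_bars)
  if (nA == 0L || nB == 0L || hi < lo) {
    stop("voices do not overlap at offset ", offset_bars)
  }
  gA <- .grid_semitones(vA)
  gB <- .grid_semitones(vB)
  idxA <- (lo * .SLOTS_PER_BAR + 1L):((hi + 1L) * .SLOTS_PER_BAR)
  idxB <- idxA + offset_bars * .SLOTS_PER_BAR
  cls <- interval_class(gA[idxA], gB[idxB])
  nb <- hi - lo + 1L
  bar_of <- rep(lo:hi, each = .SLOTS_PER_BAR)
  bar_counts <- data.frame(
    bar_a = lo:hi,
    unison = as.vector(rowsum((cls == "unison") + 0L, bar_of)),
    P4 = as.vector(rowsum((cls == "P4") + 0L, bar_of)),
    P5 = as.vector(rowsum((cls == "P5") + 0L, bar_of)),
    other = as.vector(rowsum((cls == "other") + 0L, bar_of))
  )
  n_slots <- nb * .SLOTS_PER_BAR
  f_unison <- sum(cls == "unison") / n_slots
  f_p45 <- sum(cls %in% c("P4", "P5")) / n_slots
  structure(list(offset_bars = offset_bars, overlap_bars = nb,
                 bar_counts = bar_counts, f_unison = f_unison,
                 f_p45 = f_p45, f_cons = f_unison + f_p45),
            class = "consonance_profile")
}

#' @export
print.consonance_profile <- function(x, ...) {
  cat(sprintf(paste0("consonance_profile: offset %d bars, overlap %d bars; ",
                     "f_unison = %.3f, f_p45 = %.3f, f_cons = %.3f\n"),
              x$offset_bars, x$overlap_bars, x$f_unison, x$f_p45, x$f_cons))
  invisible(x)
}

#' Best gapless alignment of two voices
#'
#' Exhaustive scan of integer bar offsets in `[-max_offset, max_offset]`
#' maximizing `f_cons`; ties go to the smaller absolute offset, then to the
#' negative offset. This replaces the by-ear trial-and-error alignment of
#' ensembles with a deterministic search.
#'
#' @param vA,vB [voice_score] objects.
#' @param max_offset maximum absolute bar offset scanned; must be smaller
#'   than both bar counts.
#' @return A list with `profile` (the winning [consonance_profile]) and
#'   `offset`.
#' @export
best_offset <- function(vA, vB, max_offset = 10L) {
  stopifnot(inherits(vA, "voice_score"), inherits(vB, "voice_score"))
  if (n_bars(vA) == 0L || n_bars(vB) == 0L) stop("empty voice")
  max_offset <- as.integer(max_offset)
  if (max_offset >= min(n_bars(vA), n_bars(vB))) {
    stop("max_offset must be smaller than both voices' bar counts")
  }
  offsets <- (-max_offset):max_offset
  # tie-break order: smaller |offset| first, negative before positive
  offsets <- offsets[order(abs(offsets), offsets)]
  best <- NULL
  for (k in offsets) {
    p <- consonance_profile(vA, vB, k)
    if (is.null(best) || p$f_cons > best$f_cons + 1e-12) best <- p
  }
  list(profile = best, offset = best$offset_bars)
}

#' Permutation test for ensemble consonance
#'
#' Quantifies whether two voices are more consonant at a given offset than
#' expected for unrelated material: the null distribution is built by
#' shuffling the bar order of `vB` (the permutation unit is the bar, i.e. the
#' codon, preserving within-bar structure) and recomputing `f_cons` at the
#' same offset. The empirical p-value is
#' `(1 + #permuted >= observed) / (n_perm + 1)`.
#'
#' @param vA,vB [voice_score] objects.
#' @param offset_bars bar offset at which the ensemble is evaluated.
#' @param n_perm number of permutations (>= 19).
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @return A `permutation_result`: list with `observed`, `null_samples`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(vA, vB, offset_bars = 0L, n_perm = 999L,
                             seed = 1L) {
  stopifnot(n_perm >= 19L)
  obs <- consonance_profile(vA, vB, offset_bars)
  if (obs$overlap_bars < 2L) stop("overlap must be at least 2 bars")
  nB <- n_bars(vB)
  # null recomputed on per-bar semitone matrices (6 slots x bars): permuting
  # matrix columns is the same shuffle as permuting vB's bars
  gA <- matrix(.grid_semitones(vA), nrow = .SLOTS_PER_BAR)
  gB <- matrix(.grid_semitones(vB), nrow = .SLOTS_PER_BAR)
  lo <- max(0L, -offset_bars)
  hi <- min(n_bars(vA) - 1L, nB - 1L - as.integer(offset_bars))
  winA <- gA[, (lo + 1L):(hi + 1L), drop = FALSE]
  colsB <- (lo + offset_bars + 1L):(hi + offset_bars + 1L)
  null_samples <- numeric(n_perm)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      perm <- sample.int(nB)
      d <- abs(winA - gB[, perm, drop = FALSE][, colsB, drop = FALSE]) %% 12L
      null_samples[r] <- mean(d == 0L | d == 5L | d == 7L)
    }
  })
  p <- (1 + sum(null_samples >= obs$f_cons - 1e-12)) / (n_perm + 1)
  structure(list(observed = obs$f_cons, null_samples = null_samples,
                 p_value = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), offset_bars = obs$offset_bars),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: observed f_cons = %.3f, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Maximal runs of unison bars
#'
#' A bar is a unison bar when all six of its slot pairs are unisons. Long
#' unison runs between sonified voices mark conserved stretches.
#'
#' @param profile a [consonance_profile].
#' @param min_len minimum run length in bars.
#' @return data.frame with `start_bar`, `end_bar` (0-based, in the
#'   coordinates of the first voice) and `length_bars`; zero rows when no run
#'   reaches `min_len`.
#' @export
unison_runs <- function(profile, min_len = 2L) {
  stopifnot(inherits(profile, "consonance_profile"))
  full <- profile$bar_counts$unison == .SLOTS_PER_BAR
  r <- rle(full)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(
    start_bar = profile$bar_counts$bar_a[starts[keep]],
    end_bar = profile$bar_counts$bar_a[ends[keep]],
    length_bars = r$lengths[keep]
  )
}

#' Melodic imitation (canon) detection
#'
#' Finds all maximal runs of identical bar tokens between two voices at every
#' positive lag: positions where `vB` restates `vA`'s material `lag` bars
#' later. In sonified coding sequences such canons flag regions of homology.
#'
#' @param vA,vB [voice_score] objects.
#' @param min_len minimum run length in bars.
#' @return data.frame with `lag_bars` (> 0), `start_index` (0-based bar in
#'   `vA`) and `length_bars`.
#' @export
imitation_lags <- function(vA, vB, min_len = 3L) {
  ta <- score_tokens(vA); tb <- score_tokens(vB)
  out <- list()
  if (length(ta) >= 1L && length(tb) >= 2L) {
    for (lag in 1L:(length(tb) - 1L)) {
      n <- min(length(ta), length(tb) - lag)
      if (n < min_len) next
      eq <- ta[seq_len(n)] == tb[seq_len(n) + lag]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_len
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          lag_bars = lag, start_index = starts[keep] - 1L,
          length_bars = r$lengths[keep])
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(lag_bars = integer(0), start_index = integer(0),
                      length_bars = integer(0)))
  }
  do.call(rbind, out)
}

#' Longest run of an identical bar
#'
#' Longest stretch of consecutive bars carrying the same melodic form (token).
#'
#' @param score a [voice_score].
#' @return Integer; 0 for an empty score.
#' @export
max_repeat_run <- function(score) {
  tok <- score_tokens(score)
  if (length(tok) == 0L) return(0L)
  max(rle(tok)$lengths)
}

#' Pairwise conservation summary of an ensemble
#'
#' For every pair of voices, finds the best gapless offset and reports the
#' consonance statistics, the longest unison run and the longest imitation.
#'
#' @param voices named list of [voice_score] objects (>= 2).
#' @param max_offset passed to [best_offset()].
#' @param min_run minimum run length for unison runs and imitations.
#' @param path optional path; when given the summary is also written as TSV.
#' @return data.frame with one row per unordered pair: `voice_a`, `voice_b`,
#'   `offset`, `f_unison`, `f_p45`, `f_cons`, `max_unison_run`,
#'   `max_imitation`.
#' @export
conservation_summary <- function(voices, max_offset = 10L, min_run = 2L,
                                 path = NULL) {
  stopifnot(is.list(voices), length(voices) >= 2L)
  labs <- names(voices)
  if (is.null(labs)) labs <- vapply(voices, function(v) v$label, "")
  pairs <- utils::combn(length(voices), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- voices[[ij[1]]]; b <- voices[[ij[2]]]
    bo <- best_offset(a, b, max_offset)
    runs <- unison_runs(bo$profile, min_len = 1L)
    im <- imitation_lags(a, b, min_len = 1L)
    data.frame(
      voice_a = labs[ij[1]], voice_b = labs[ij[2]], offset = bo$offset,
      f_unison = bo$profile$f_unison, f_p45 = bo$profile$f_p45,
      f_cons = bo$profile$f_cons,
      max_unison_run = if (nrow(runs)) max(runs$length_bars) else 0L,
      max_imitation = if (nrow(im)) max(im$length_bars) else 0L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Symmetric pairwise matrix from a conservation summary
#'
#' @param summary output of [conservation_summary()].
#' @param stat column to spread, e.g. `"f_unison"`.
#' @return Symmetric numeric matrix with voice labels as dimnames; the
#'   diagonal is `NA`.
#' @export
pairwise_matrix <- function(summary, stat = "f_unison") {
  labs <- unique(c(summary$voice_a, summary$voice_b))
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_len(nrow(summary))) {
    m[summary$voice_a[i], summary$voice_b[i]] <- summary[[stat]][i]
    m[summary$voice_b[i], summary$voice_a[i]] <- summary[[stat]][i]
  }
  m
}
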