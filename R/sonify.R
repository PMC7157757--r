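#' Construct a voice score
#'
#' A `voice_score` is one melodic voice: an ordered set of bars, one per
#' codon, each bar holding the codon, its melodic formula (solfège letters)
#' and its note durations in beats. Normally produced by [sonify()].
#'
#' @param bars data.frame with columns `bar_index` (0-based), `codon`,
#'   `formula`, `durations` (comma-separated beats).
#' @param label display name of the voice.
#' @param source_id identifier of the source sequence.
#' @param mapping_id identifier of the codon mapping used.
#' @return A `voice_score` object.
#' @export
voice_score <- function(bars, label = "voice", source_id = label,
                        mapping_id = "custom") {
  stopifnot(is.data.frame(bars),
            all(c("bar_index", "codon", "formula", "durations") %in% names(bars)))
  if (nrow(bars) > 0L) {
    if (!identical(as.integer(bars$bar_index), seq_len(nrow(bars)) - 1L)) {
      stop("bars must be contiguous from index 0")
    }
    sums <- vapply(strsplit(bars$durations, ",", fixed = TRUE),
                   function(d) sum(as.numeric(d)), 0)
    if (any(abs(sums - 3) > 1e-9)) {
      stop("bar durations must sum to 3 beats; offending bar_index: ",
           paste(bars$bar_index[abs(sums - 3) > 1e-9], collapse = ", "))
    }
  }
  rownames(bars) <- NULL
  structure(list(label = label, source_id = source_id,
                 mapping_id = mapping_id, bars = bars),
            class = "voice_score")
}

#' Render one codon as a bar
#'
#' @param codon an RNA or DNA triplet (`T` is transcribed to `U`).
#' @param mapping a [codon_mapping].
#' @param index 0-based position of the bar in its score.
#' @return A list with `bar_index`, `codon`, `pitches` (degree letters),
#'   `durations` (beats; they sum to 3).
#' @examples
#' codon_to_bar("UGC", default_mapping())
#' @export
codon_to_bar <- function(codon, mapping = default_mapping(), index = 0L) {
  codon <- .normalize_codons(codon)
  if (!grepl("^[ACGU]{3}$", codon)) {
    stop("degenerate or invalid base in codon: ", codon)
  }
  i <- match(codon, mapping$codon)
  r <- rhythm_for(codon, mapping)
  list(bar_index = as.integer(index), codon = codon,
       pitches = strsplit(mapping$formula[i], "")[[1]],
       durations = r$durations)
}

#' Sonify a coding sequence
#'
#' Translates a nucleotide sequence, read in frame from its first base, into
#' a musical score with one 3/4 bar per codon. Pitches are the codon's
#' melodic formula; the rhythm follows the fixed bar-filling rules (see
#' [rhythm_for()]). Stop codons are sonified like any other codon.
#'
#' @param sequence nucleotide string over `A`,`C`,`G`,`T`,`U`
#'   (case-insensitive; whitespace ignored).
#' @param mapping a [codon_mapping].
#' @param frame_policy `"strict"` (default) errors if the length is not a
#'   multiple of 3; `"trim"` drops the incomplete tail with a warning.
#' @param label,source_id identifiers stored in the score.
#' @return A [voice_score] with `floor(nchar(sequence) / 3)` bars.
#' @examples
#' s <- sonify("TGCGGATCT")
#' s$bars
#' @export
sonify <- function(sequence, mapping = default_mapping(),
                   frame_policy = c("strict", "trim"),
                   label = "voice", source_id = label) {
  frame_policy <- match.arg(frame_policy)
  stopifnot(inherits(mapping, "codon_mapping"), is.character(sequence),
            length(sequence) == 1L)
  seq <- gsub("[[:space:]]", "", toupper(sequence))
  if (grepl("[^ACGTU]", seq)) {
    bad <- unique(strsplit(gsub("[ACGTU]", "", seq), "")[[1]])
    stop("sequence contains invalid characters: ", paste(bad, collapse = ", "))
  }
  rem <- nchar(seq) %% 3L
  if (rem != 0L) {
    if (frame_policy == "strict") {
      stop("sequence length ", nchar(seq), " is not a multiple of 3 ",
           "(use frame_policy = \"trim\" to drop the incomplete tail)")
    }
    warning("dropping incomplete trailing ", rem, " base(s)")
    seq <- substr(seq, 1L, nchar(seq) - rem)
  }
  n <- nchar(seq) %/% 3L
  if (n == 0L) {
    bars <- data.frame(bar_index = integer(0), codon = character(0),
                       formula = character(0), durations = character(0),
                       stringsAsFactors = FALSE)
    return(voice_score(bars, label, source_id, attr(mapping, "mapping_id")))
  }
  codons <- .normalize_codons(substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n)))
  i <- match(codons, mapping$codon)
  bars <- data.frame(bar_index = seq_len(n) - 1L, codon = codons,
                     formula = mapping$formula[i],
                     durations = mapping$durations[i],
                     stringsAsFactors = FALSE)
  voice_score(bars, label, source_id, attr(mapping, "mapping_id"))
}

#' Recover the coding sequence from a score
#'
#' Inverts [sonify()]: maps each bar's (pitches, durations) back to its codon.
#' Requires the mapping to be injective over the bars present; with a
#' non-injective mapping the ambiguous codons are named in the error.
#'
#' @param score a [voice_score].
#' @param mapping the [codon_mapping] the score was produced with.
#' @return The RNA sequence (over `A`,`C`,`G`,`U`) of the score.
#' @examples
#' detokenize(sonify("UGCGGAUCU"))  # "UGCGGAUCU"
#' @export
detokenize <- function(score, mapping = default_mapping()) {
  stopifnot(inherits(score, "voice_score"), inherits(mapping, "codon_mapping"))
  if (nrow(score$bars) == 0L) return("")
  map_key <- paste(mapping$formula, mapping$durations)
  dup <- map_key %in% map_key[duplicated(map_key)]
  bar_key <- paste(score$bars$formula, score$bars$durations)
  amb <- bar_key %in% map_key[dup]
  if (any(amb)) {
    stop("mapping is not injective; cannot invert bars matching codons: ",
         paste(sort(unique(mapping$codon[map_key %in% bar_key[amb] & dup])),
               collapse = ", "))
  }
  i <- match(bar_key, map_key)
  if (anyNA(i)) {
    stop("bar(s) not derivable from the mapping at bar_index: ",
         paste(score$bars$bar_index[is.na(i)], collapse = ", "))
  }
  paste(mapping$codon[i], collapse = "")
}

#' Bar tokens of a score
#'
#' One string per bar combining melodic formula and rhythm, e.g. `"SL|1.5,1.5"`.
#' Two bars are the same musical material iff their tokens are equal; tokens
#' are the comparison unit for repeat runs and canon detection.
#'
#' @param score a [voice_score].
#' @return Character vector, one token per bar.
#' @export
score_tokens <- function(score) {
  stopifnot(inherits(score, "voice_score"))
  if (nrow(score$bars) == 0L) return(character(0))
  paste(score$bars$formula, score$bars$durations, sep = "|")
}

#' Number of bars in a score
#' @param score a [voice_score].
#' @return Integer bar count.
#' @export
n_bars <- function(score) nrow(score$bars)

#' @export
print.voice_score <- function(x, ...) {
  cat(sprintf("voice_score '%s' (%s): %d bars in 3/4, mapping '%s'\n",
              x$label, x$source_id, nrow(x$bars), x$mapping_id))
  if (nrow(x$bars) > 0) print.data.frame(head(x$bars, 6))
  if (nrow(x$bars) > 6) cat("...\n")
  invisible(x)
}
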