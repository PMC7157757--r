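#' Solfège degrees used in codon melodic formulas
#'
#' The seven diatonic scale degrees Do-Re-Mi-Fa-Sol-La-Si, written with the
#' single letters D, R, M, F, S, L, T. Each degree carries a fixed semitone
#' offset above the tonic (major scale: 0, 2, 4, 5, 7, 9, 11), so a melodic
#' formula such as `"SMR"` realizes to concrete pitches once a tonic is chosen.
#'
#' @return A data.frame with one row per degree and columns `letter`,
#'   `degree_index` (1-7) and `semitone_offset`.
#' @examples
#' solfege_degrees()
#' @export
solfege_degrees <- function() {
  data.frame(
    letter = c("D", "R", "M", "F", "S", "L", "T"),
    degree_index = 1:7,
    semitone_offset = c(0L, 2L, 4L, 5L, 7L, 9L, 11L),
    stringsAsFactors = FALSE
  )
}

# letter -> semitone offset, as a fast named lookup
.SOLFEGE_SEMITONES <- c(D = 0L, R = 2L, M = 4L, F = 5L, S = 7L, L = 9L, T = 11L)
.SOLFEGE_LETTERS <- names(.SOLFEGE_SEMITONES)

#' Semitone offsets of a melodic formula
#'
#' @param formula character vector of concatenated degree letters, e.g. "SMR".
#' @return A list of integer vectors, one per formula, with semitone offsets
#'   relative to the tonic.
#' @examples
#' formula_semitones("SMR")
#' @export
formula_semitones <- function(formula) {
  lapply(strsplit(formula, ""), function(ltrs) {
    bad <- setdiff(ltrs, .SOLFEGE_LETTERS)
    if (length(bad) > 0L) {
      stop("unknown solfege letter(s): ", paste(unique(bad), collapse = ", "))
    }
    unname(.SOLFEGE_SEMITONES[ltrs])
  })
}

# Chromatic pitch name ("C4", "F#3", "Bb5") -> MIDI note number.
.tonic_midi <- function(tonic) {
  m <- regmatches(tonic, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)$", tonic))[[1]]
  if (length(m) == 0L) stop("invalid pitch name: ", tonic)
  base <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)
  pc <- base[[toupper(m[2])]] + switch(m[3], "#" = 1L, "b" = -1L, 0L)
  pc + 12L * (as.integer(m[4]) + 1L)
}

# MIDI note number -> MusicXML spelling (step, alter, octave), sharps only.
.midi_spelling <- function(midi) {
  steps <- c("C", "C", "D", "D", "E", "F", "F", "G", "G", "A", "A", "B")
  alters <- c(0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 1L, 0L)
  pc <- midi %% 12L
  list(step = steps[pc + 1L], alter = alters[pc + 1L], octave = midi %/% 12L - 1L)
}
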