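#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()]: records keep file order,
#' ids are the header up to the first whitespace, sequences are uppercased,
#' and gap/whitespace characters are stripped (with a warning when gaps were
#' present).
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  seqs <- toupper(as.character(set))
  if (any(grepl("-", seqs, fixed = TRUE))) {
    warning("gap characters stripped from FASTA sequence(s)")
  }
  seqs <- gsub("[-[:space:]]", "", seqs)
  ids <- sub("\\s.*$", "", names(set))
  stats::setNames(unname(seqs), ids)
}

#' Rendering options for score export
#'
#' The source method states neither tempo nor key; both are presentation-only
#' defaults here: 90 beats per minute and a C4 tonic, all pitches within a
#' single octave above the tonic.
#'
#' @param tempo beats per minute (> 0).
#' @param tonic pitch name with octave, e.g. `"C4"`, `"F#3"`.
#' @param one_part_per_voice logical; MusicXML gets one part per voice.
#' @return A `render_options` list with an added `tonic_midi` field.
#' @export
render_options <- function(tempo = 90, tonic = "C4", one_part_per_voice = TRUE) {
  stopifnot(tempo > 0)
  structure(list(tempo = tempo, tonic = tonic, tonic_midi = .tonic_midi(tonic),
                 one_part_per_voice = isTRUE(one_part_per_voice)),
            class = "render_options")
}

#' Write a score in the lossless token format
#'
#' One TSV row per bar (`bar_index`, `codon`, `formula`, `durations`), with
#' `#`-prefixed header lines holding the voice metadata. Writing the same
#' score twice yields identical bytes; [read_tokens()] inverts it exactly.
#'
#' @param score a [voice_score].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tokens <- function(score, path) {
  stopifnot(inherits(score, "voice_score"))
  con <- file(path, open = "wb")  # binary mode: identical bytes on all platforms
  on.exit(close(con))
  writeLines(c(
    paste0("#label=", score$label),
    paste0("#source_id=", score$source_id),
    paste0("#mapping_id=", score$mapping_id),
    "bar_index\tcodon\tformula\tdurations"), con, sep = "\n")
  if (nrow(score$bars) > 0L) {
    writeLines(paste(score$bars$bar_index, score$bars$codon,
                     score$bars$formula, score$bars$durations, sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a score from the token format
#'
#' Validates every bar (durations must sum to 3 beats) and reports malformed
#' lines by line number. Rows out of bar order are re-sorted with a warning.
#'
#' @param path file written by [write_tokens()].
#' @return A [voice_score].
#' @export
read_tokens <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getmeta <- function(key, default) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^#", key, "="), "", hit[1]) else default
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L || body[1] != "bar_index\tcodon\tformula\tdurations") {
    stop("token file missing header line")
  }
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  line_no <- match(rows, lines)
  parts <- strsplit(rows, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 4L
  if (any(bad)) {
    stop("malformed token line(s) at line ", paste(line_no[bad], collapse = ", "))
  }
  bars <- data.frame(
    bar_index = suppressWarnings(as.integer(vapply(parts, `[`, "", 1L))),
    codon = vapply(parts, `[`, "", 2L),
    formula = vapply(parts, `[`, "", 3L),
    durations = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE)
  if (anyNA(bars$bar_index)) {
    stop("malformed bar_index at line ",
         paste(line_no[is.na(bars$bar_index)], collapse = ", "))
  }
  sums <- vapply(strsplit(bars$durations, ",", fixed = TRUE),
                 function(d) sum(suppressWarnings(as.numeric(d))), 0)
  if (anyNA(sums) || any(abs(sums - 3) > 1e-9)) {
    stop("bar durations do not sum to 3 beats at line ",
         paste(line_no[is.na(sums) | abs(sums - 3) > 1e-9], collapse = ", "))
  }
  if (is.unsorted(bars$bar_index, strictly = TRUE)) {
    warning("bar_index out of order; rows re-sorted")
    bars <- bars[order(bars$bar_index), ]
  }
  if (!identical(as.integer(bars$bar_index), seq_len(nrow(bars)) - 1L)) {
    stop("bar_index values are not contiguous from 0")
  }
  voice_score(bars, label = getmeta("label", "voice"),
              source_id = getmeta("source_id", "unknown"),
              mapping_id = getmeta("mapping_id", "custom"))
}
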