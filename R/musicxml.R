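# MusicXML 3.1 export (and a reader for the subset this package writes).
# One part per voice, every measure in 3/4, divisions = 2 so the eighth note
# is one division. Pitches realize the solfège degrees from the tonic.

.NOTE_TYPES <- data.frame(
  beats = c(3, 2, 1.5, 1, 0.5),
  type = c("half", "half", "quarter", "quarter", "eighth"),
  dot = c(TRUE, FALSE, TRUE, FALSE, FALSE)
)

#' Write voices as MusicXML
#'
#' @param scores a [voice_score] or list of them.
#' @param path output file.
#' @param options a [render_options()].
#' @return `path`, invisibly.
#' @seealso [read_musicxml()] for re-importing pitch/duration content.
#' @export
write_musicxml <- function(scores, path, options = render_options()) {
  if (inherits(scores, "voice_score")) scores <- list(scores)
  stopifnot(length(scores) > 0L,
            all(vapply(scores, inherits, TRUE, "voice_score")),
            inherits(options, "render_options"))
  doc <- xml2::xml_new_root("score-partwise", version = "3.1")
  plist <- xml2::xml_add_child(doc, "part-list")
  for (i in seq_along(scores)) {
    sp <- xml2::xml_add_child(plist, "score-part", id = paste0("P", i))
    xml2::xml_add_child(sp, "part-name", scores[[i]]$label)
  }
  for (i in seq_along(scores)) {
    part <- xml2::xml_add_child(doc, "part", id = paste0("P", i))
    bars <- scores[[i]]$bars
    for (bi in seq_len(max(1L, nrow(bars)))) {
      meas <- xml2::xml_add_child(part, "measure", number = as.character(bi))
      if (bi == 1L) {
        at <- xml2::xml_add_child(meas, "attributes")
        xml2::xml_add_child(at, "divisions", "2")
        tm <- xml2::xml_add_child(at, "time")
        xml2::xml_add_child(tm, "beats", "3")
        xml2::xml_add_child(tm, "beat-type", "4")
        cl <- xml2::xml_add_child(at, "clef")
        xml2::xml_add_child(cl, "sign", "G")
        xml2::xml_add_child(cl, "line", "2")
        snd <- xml2::xml_add_child(meas, "sound")
        xml2::xml_set_attr(snd, "tempo", format(options$tempo))
      }
      if (nrow(bars) == 0L) break
      ltrs <- strsplit(bars$formula[bi], "")[[1]]
      durs <- .parse_durations(bars$durations[bi])
      for (k in seq_along(ltrs)) {
        midi <- options$tonic_midi + .SOLFEGE_SEMITONES[[ltrs[k]]]
        sp <- .midi_spelling(midi)
        note <- xml2::xml_add_child(meas, "note")
        p <- xml2::xml_add_child(note, "pitch")
        xml2::xml_add_child(p, "step", sp$step)
        if (sp$alter != 0L) xml2::xml_add_child(p, "alter", as.character(sp$alter))
        xml2::xml_add_child(p, "octave", as.character(sp$octave))
        xml2::xml_add_child(note, "duration", as.character(as.integer(2 * durs[k])))
        row <- which(abs(.NOTE_TYPES$beats - durs[k]) < 1e-9)[1]
        xml2::xml_add_child(note, "type", .NOTE_TYPES$type[row])
        if (.NOTE_TYPES$dot[row]) xml2::xml_add_child(note, "dot")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read pitch/duration content back from MusicXML
#'
#' Parses the subset of MusicXML that [write_musicxml()] emits and returns,
#' per part, the realized MIDI note numbers and durations in beats -- enough
#' to verify that export is lossless on musical content.
#'
#' @param path MusicXML file.
#' @return Named list (one element per part) of data.frames with columns
#'   `midi` and `beats`, plus a `measures` attribute per part.
#' @export
read_musicxml <- function(path) {
  doc <- xml2::read_xml(path)
  base <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)
  parts <- xml2::xml_find_all(doc, "part")
  names <- xml2::xml_text(xml2::xml_find_all(doc, "part-list/score-part/part-name"))
  out <- lapply(parts, function(part) {
    divisions <- as.numeric(xml2::xml_text(
      xml2::xml_find_first(part, ".//attributes/divisions")))
    notes <- xml2::xml_find_all(part, ".//note")
    step <- xml2::xml_text(xml2::xml_find_all(notes, "pitch/step"))
    alter <- vapply(notes, function(n) {
      a <- xml2::xml_find_first(n, "pitch/alter")
      if (is.na(a)) 0L else as.integer(xml2::xml_text(a))
    }, 0L)
    oct <- as.integer(xml2::xml_text(xml2::xml_find_all(notes, "pitch/octave")))
    dur <- as.numeric(xml2::xml_text(xml2::xml_find_all(notes, "duration")))
    df <- data.frame(midi = base[step] + alter + 12L * (oct + 1L),
                     beats = dur / divisions, row.names = NULL)
    attr(df, "measures") <- length(xml2::xml_find_all(part, "measure"))
    df
  })
  stats::setNames(out, names)
}
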