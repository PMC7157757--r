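# Minimal Standard MIDI File (type 1) writer and reader. No MIDI package is
# available in R, so the subset needed here is implemented directly: one
# tempo track, one note track per voice, 480 ticks per quarter note, no
# running status. The reader parses exactly this subset (plus unknown meta
# events, which it skips) -- enough to round-trip onsets, pitches and the
# tempo-scaled timing grid.

.MIDI_DIVISION <- 480L

.vlq <- function(x) {
  # variable-length quantity encoding
  x <- as.integer(x)
  stopifnot(x >= 0L)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  # set continuation bit on all but the last byte
  if (length(bytes) > 1L) {
    bytes[-length(bytes)] <- bitwOr(bytes[-length(bytes)], 128L)
  }
  as.raw(bytes)
}

.be <- function(x, width) {
  # big-endian unsigned integer of given byte width
  out <- raw(width)
  for (i in width:1) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

.chunk <- function(tag, payload) {
  c(charToRaw(tag), .be(length(payload), 4L), payload)
}

#' Write voices as a Standard MIDI File (type 1)
#'
#' One track per voice plus a leading tempo track; note numbers are the tonic
#' MIDI number plus the degree's semitone offset, and durations are scaled by
#' the tempo (480 ticks per quarter note).
#'
#' @param scores a [voice_score] or list of them.
#' @param path output file.
#' @param options a [render_options()].
#' @return `path`, invisibly.
#' @export
write_midi <- function(scores, path, options = render_options()) {
  if (inherits(scores, "voice_score")) scores <- list(scores)
  stopifnot(length(scores) > 0L,
            all(vapply(scores, inherits, TRUE, "voice_score")),
            inherits(options, "render_options"))
  usec_per_qn <- as.integer(round(60e6 / options$tempo))
  tempo_track <- c(
    .vlq(0L), as.raw(c(0xFF, 0x51, 0x03)), .be(usec_per_qn, 3L),
    .vlq(0L), as.raw(c(0xFF, 0x58, 0x04, 0x03, 0x02, 0x18, 0x08)),  # 3/4
    .vlq(0L), as.raw(c(0xFF, 0x2F, 0x00)))
  tracks <- lapply(scores, function(sc) {
    ev <- list()
    name <- charToRaw(sc$label)
    ev[[1]] <- c(.vlq(0L), as.raw(c(0xFF, 0x03)), .vlq(length(name)), name)
    if (nrow(sc$bars) > 0L) {
      ltrs <- strsplit(sc$bars$formula, "")
      durs <- lapply(strsplit(sc$bars$durations, ",", fixed = TRUE), as.numeric)
      for (b in seq_len(nrow(sc$bars))) {
        for (k in seq_along(ltrs[[b]])) {
          note <- options$tonic_midi + .SOLFEGE_SEMITONES[[ltrs[[b]][k]]]
          ticks <- as.integer(round(durs[[b]][k] * .MIDI_DIVISION))
          ev[[length(ev) + 1L]] <- c(.vlq(0L), as.raw(c(0x90, note, 64L)))
          ev[[length(ev) + 1L]] <- c(.vlq(ticks), as.raw(c(0x80, note, 0L)))
        }
      }
    }
    ev[[length(ev) + 1L]] <- c(.vlq(0L), as.raw(c(0xFF, 0x2F, 0x00)))
    do.call(c, ev)
  })
  header <- .chunk("MThd", c(.be(1L, 2L), .be(length(scores) + 1L, 2L),
                             .be(.MIDI_DIVISION, 2L)))
  body <- c(header, .chunk("MTrk", tempo_track),
            do.call(c, lapply(tracks, .chunk, tag = "MTrk")))
  writeBin(body, path)
  invisible(path)
}

#' Read a Standard MIDI File written by this package
#'
#' @param path MIDI file (type 0/1, no running status).
#' @return List with `division` (ticks per quarter), `tempo` (beats per
#'   minute), and `tracks`: per note track a data.frame with `note`,
#'   `onset_ticks`, `duration_ticks`, `onset_sec`, `duration_sec`, plus the
#'   track `label`.
#' @export
read_midi <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u <- function(bytes) sum(as.integer(bytes) * 256^((length(bytes) - 1):0))
  stopifnot(rawToChar(raw[1:4]) == "MThd")
  ntrk <- u(raw[11:12]); division <- u(raw[13:14])
  pos <- 15L
  tempo_usec <- 500000
  tracks <- list()
  read_vlq <- function() {
    val <- 0L
    repeat {
      b <- as.integer(raw[pos]); pos <<- pos + 1L
      val <- val * 128L + b %% 128L
      if (b < 128L) break
    }
    val
  }
  for (t in seq_len(ntrk)) {
    stopifnot(rawToChar(raw[pos:(pos + 3L)]) == "MTrk")
    len <- u(raw[(pos + 4L):(pos + 7L)])
    pos <- pos + 8L
    end <- pos + len
    tick <- 0L
    label <- ""
    on_at <- list()
    notes <- data.frame(note = integer(0), onset_ticks = integer(0),
                        duration_ticks = integer(0))
    while (pos < end) {
      tick <- tick + read_vlq()
      status <- as.integer(raw[pos]); pos <- pos + 1L
      if (status == 0xFF) {
        type <- as.integer(raw[pos]); pos <- pos + 1L
        mlen <- read_vlq()
        payload <- if (mlen > 0L) raw[pos:(pos + mlen - 1L)] else raw(0)
        pos <- pos + mlen
        if (type == 0x51) tempo_usec <- u(payload)
        if (type == 0x03) label <- rawToChar(payload)
      } else if (bitwAnd(status, 0xF0) %in% c(0x90, 0x80)) {
        note <- as.integer(raw[pos]); vel <- as.integer(raw[pos + 1L])
        pos <- pos + 2L
        key <- as.character(note)
        if (bitwAnd(status, 0xF0) == 0x90 && vel > 0L) {
          on_at[[key]] <- tick
        } else if (!is.null(on_at[[key]])) {
          notes <- rbind(notes, data.frame(note = note,
                                           onset_ticks = on_at[[key]],
                                           duration_ticks = tick - on_at[[key]]))
          on_at[[key]] <- NULL
        }
      } else {
        stop("unsupported MIDI event 0x", format(as.hexmode(status)),
             " (this reader supports files written by write_midi)")
      }
    }
    sec_per_tick <- tempo_usec / 1e6 / division
    if (nrow(notes) > 0L) {
      notes$onset_sec <- notes$onset_ticks * sec_per_tick
      notes$duration_sec <- notes$duration_ticks * sec_per_tick
    }
    attr(notes, "label") <- label
    tracks[[t]] <- notes
  }
  list(division = division, tempo = 60e6 / tempo_usec,
       tracks = tracks[-1])  # drop the tempo track
}
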