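#' Rendering configuration for MIDI output
#'
#' All stimuli are isochronous piano tones: equal inter-onset intervals and
#' equal durations. Accented targets are rendered at velocity
#' `velocity + accent_delta`; all other notes at `velocity`.
#'
#' @param ioi_ms Inter-onset interval in milliseconds. Default 500.
#' @param duration_ms Note duration in milliseconds (must not exceed
#'   `ioi_ms`). Default 450.
#' @param velocity Base MIDI velocity 1-127. Default 80.
#' @param accent_delta Velocity increment for accented targets. Default 32.
#' @param program General MIDI program number (0 = acoustic grand piano).
#' @param ppq Pulses per quarter note. Default 480.
#' @param tempo_us Microseconds per quarter note. Default 500000 (120 bpm).
#' @return A `render_config` list.
#' @export
render_config <- function(ioi_ms = 500, duration_ms = 450, velocity = 80L,
                          accent_delta = 32L, program = 0L, ppq = 480L,
                          tempo_us = 500000L) {
  stopifnot(duration_ms <= ioi_ms, velocity >= 1, velocity <= 127,
            velocity + accent_delta <= 127, program >= 0, program <= 127)
  structure(list(ioi_ms = ioi_ms, duration_ms = duration_ms,
                 velocity = as.integer(velocity),
                 accent_delta = as.integer(accent_delta),
                 program = as.integer(program), ppq = as.integer(ppq),
                 tempo_us = as.integer(tempo_us)),
            class = "render_config")
}

ms_to_ticks <- function(ms, cfg) {
  as.integer(round(ms * cfg$ppq * 1000 / cfg$tempo_us))
}

# --- variable-length quantities ---------------------------------------------

encode_vlq <- function(x) {
  stopifnot(x >= 0)
  bytes <- as.integer(x %% 128L)
  x <- x %/% 128L
  while (x > 0) {
    bytes <- c(as.integer(x %% 128L), bytes)
    x <- x %/% 128L
  }
  n <- length(bytes)
  if (n > 1L) bytes[seq_len(n - 1L)] <- bytes[seq_len(n - 1L)] + 128L
  as.raw(bytes)
}

decode_vlq <- function(bytes, pos) {
  val <- 0
  repeat {
    b <- as.integer(bytes[pos]); pos <- pos + 1L
    val <- val * 128 + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

uint_bytes <- function(x, n) {
  out <- raw(n)
  for (i in n:1) { out[i] <- as.raw(x %% 256); x <- x %/% 256 }
  out
}

# --- writer ------------------------------------------------------------------

#' Render a melody to Standard MIDI File bytes
#'
#' Produces a single-track (format 0) MIDI file: one note per scale degree at
#' a constant inter-onset interval, rendered through the given pitch mapping.
#' Accented targets receive velocity `velocity + accent_delta`; agrammatical
#' variants are rendered with the degree 5/6 pitch swap (applied by
#' [melody_pitches()]). Output is byte-identical for identical inputs.
#'
#' @param melody A `melody_record`.
#' @param mapping A `pitch_mapping`.
#' @param cfg A [render_config()].
#' @return A raw vector of MIDI file bytes.
#' @seealso [write_melody_midi()], [read_midi_notes()]
#' @export
render_midi <- function(melody, mapping, cfg = render_config()) {
  pitches <- melody_pitches(melody, mapping)
  if (any(pitches < 0L | pitches > 127L))
    abort("rendered pitch outside MIDI range 0-127")
  vel <- rep(cfg$velocity, length(pitches))
  acc <- melody$targets$position[melody$targets$accented]
  vel[acc] <- cfg$velocity + cfg$accent_delta

  ioi <- ms_to_ticks(cfg$ioi_ms, cfg)
  dur <- ms_to_ticks(cfg$duration_ms, cfg)
  gap <- ioi - dur

  ev <- list(
    c(encode_vlq(0L), as.raw(c(0xFF, 0x51, 0x03)), uint_bytes(cfg$tempo_us, 3L)),
    c(encode_vlq(0L), as.raw(c(0xC0, cfg$program)))
  )
  for (i in seq_along(pitches)) {
    delta_on <- if (i == 1L) 0L else gap
    ev[[length(ev) + 1L]] <- c(encode_vlq(delta_on),
                               as.raw(c(0x90, pitches[i], vel[i])))
    ev[[length(ev) + 1L]] <- c(encode_vlq(dur),
                               as.raw(c(0x80, pitches[i], 0x40)))
  }
  ev[[length(ev) + 1L]] <- c(encode_vlq(0L), as.raw(c(0xFF, 0x2F, 0x00)))
  track <- do.call(c, ev)

  c(charToRaw("MThd"), uint_bytes(6L, 4L),
    uint_bytes(0L, 2L), uint_bytes(1L, 2L), uint_bytes(cfg$ppq, 2L),
    charToRaw("MTrk"), uint_bytes(length(track), 4L), track)
}

#' Write a melody to a MIDI file on disk
#'
#' @inheritParams render_midi
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_melody_midi <- function(melody, mapping, path, cfg = render_config()) {
  writeBin(render_midi(melody, mapping, cfg), path)
  invisible(path)
}

# --- reader (for round-trip verification) ------------------------------------

#' Read the note events of a MIDI file
#'
#' A small Standard MIDI File parser sufficient to round-trip the files this
#' package writes (and simple single-track files generally): it walks one or
#' more MTrk chunks, handles running status, and pairs note-on events with
#' the matching note-off (or zero-velocity note-on).
#'
#' @param path Path to a MIDI file, or a raw vector of MIDI bytes.
#' @return A tibble with one row per note: `onset_ticks`, `pitch`,
#'   `velocity`, `duration_ticks`.
#' @export
read_midi_notes <- function(path) {
  bytes <- if (is.raw(path)) path else readBin(path, "raw", file.size(path))
  stopifnot(rawToChar(bytes[1:4]) == "MThd")
  n_tracks <- as.integer(bytes[11]) * 256L + as.integer(bytes[12])
  pos <- 15L
  notes <- list()
  for (t in seq_len(n_tracks)) {
    stopifnot(rawToChar(bytes[pos:(pos + 3L)]) == "MTrk")
    track_len <- sum(as.integer(bytes[pos + 4:7]) * 256^(3:0))
    pos <- pos + 8L
    end <- pos + track_len
    time <- 0
    status <- NULL
    open <- list()
    while (pos < end) {
      d <- decode_vlq(bytes, pos); pos <- d$pos
      time <- time + d$value
      b <- as.integer(bytes[pos])
      if (b >= 128L) { status <- b; pos <- pos + 1L }
      if (status == 255L) {                 # meta event
        pos <- pos + 1L                     # type byte
        d <- decode_vlq(bytes, pos); pos <- d$pos + d$value
      } else if (status >= 240L) {          # sysex
        d <- decode_vlq(bytes, pos); pos <- d$pos + d$value
      } else {
        kind <- status %/% 16L
        n_data <- if (kind %in% c(12L, 13L)) 1L else 2L
        data <- as.integer(bytes[pos + seq_len(n_data) - 1L])
        pos <- pos + n_data
        key <- as.character(data[1])
        if (kind == 9L && data[2] > 0L) {
          open[[key]] <- c(time, data[2])
        } else if (kind == 8L || (kind == 9L && data[2] == 0L)) {
          if (!is.null(open[[key]])) {
            notes[[length(notes) + 1L]] <-
              c(open[[key]][1], data[1], open[[key]][2],
                time - open[[key]][1])
            open[[key]] <- NULL
          }
        }
      }
    }
  }
  m <- do.call(rbind, notes)
  out <- tibble::tibble(
    onset_ticks = m[, 1], pitch = as.integer(m[, 2]),
    velocity = as.integer(m[, 3]), duration_ticks = m[, 4]
  )
  dplyr::arrange(out, .data$onset_ticks)
}
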