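#' Define an asymmetric hexascale
#'
#' A hexascale is a six-note scale specified by its interval pattern in
#' semitones, which must sum to an octave (12) and be rotationally
#' asymmetric: no nonzero rotation of the pattern reproduces it. Asymmetry
#' means every window position on the repeating pitch lattice yields a
#' distinct pattern of intervals between scale degrees, which is what lets
#' listeners locate themselves in the scale after brief exposure.
#'
#' @param pattern Six positive integers (semitones) summing to 12.
#' @param anchor_pitch MIDI note number of the lattice origin. Default 60
#'   (middle C).
#' @return A `hexascale` object.
#' @examples
#' hexascale()                 # default pattern 1,2,2,1,3,3
#' try(hexascale(rep(2, 6)))   # whole-tone pattern: rotationally symmetric
#' @export
hexascale <- function(pattern = c(1L, 2L, 2L, 1L, 3L, 3L), anchor_pitch = 60L) {
  pattern <- as.integer(pattern)
  if (length(pattern) != 6L || any(pattern < 1L))
    abort("hexascale pattern must be 6 intervals of at least 1 semitone")
  if (sum(pattern) != 12L)
    abort("hexascale pattern must sum to 12 semitones")
  for (r in 1:5)
    if (identical(pattern, pattern[((seq_len(6) - 1L + r) %% 6L) + 1L]))
      abort("hexascale pattern must be rotationally asymmetric")
  structure(list(pattern = pattern, anchor_pitch = as.integer(anchor_pitch)),
            class = "hexascale")
}

#' Build the scale-degree-to-pitch mapping for one tonic condition
#'
#' Scale degrees are mapped to pitches through a sliding window on the
#' repeating hexascale lattice. The window position (`tonic_lattice_index`,
#' 0-5) fixes the pitch of scale degree 1 and hence, through the rotated
#' interval pattern, the pitches of degrees 2-6; degree 7 is degree 1
#' repeated one octave higher. The six window positions are the experiment's
#' six tonic listening conditions, each with a distinct interval pattern
#' between degrees.
#'
#' @param scale A [hexascale()].
#' @param tonic_lattice_index Integer 0-5: window start on the lattice.
#' @return A `pitch_mapping` object with `degree_to_pitch` (named integer
#'   vector, degrees 1-7 to MIDI note numbers).
#' @examples
#' m <- build_pitch_mapping(hexascale(), 0)
#' m$degree_to_pitch  # 60 61 63 65 66 69 72
#' @export
build_pitch_mapping <- function(scale, tonic_lattice_index = 0L) {
  stopifnot(inherits(scale, "hexascale"))
  idx <- as.integer(tonic_lattice_index)
  if (idx < 0L || idx > 5L)
    abort("tonic_lattice_index must be between 0 and 5")
  rotated <- scale$pattern[((idx + 0:5) %% 6L) + 1L]
  p1 <- scale$anchor_pitch + sum(scale$pattern[seq_len(idx)])
  pitches <- as.integer(p1 + c(0L, cumsum(rotated)))
  if (any(pitches < 0L | pitches > 127L))
    abort("mapping places pitches outside the MIDI range 0-127")
  structure(
    list(tonic_lattice_index = idx,
         degree_to_pitch = setNames(pitches, DEGREES),
         scale = scale),
    class = "pitch_mapping"
  )
}

#' @export
print.pitch_mapping <- function(x, ...) {
  cat(sprintf("<pitch_mapping> tonic window %d\n", x$tonic_lattice_index))
  print(x$degree_to_pitch)
  invisible(x)
}

#' @rdname build_pitch_mapping
#' @param x A `pitch_mapping`.
#' @param ... Unused.
#' @method tidy pitch_mapping
#' @export
tidy.pitch_mapping <- function(x, ...) {
  tibble::tibble(degree = DEGREES,
                 pitch = unname(x$degree_to_pitch))
}

#' Rendered pitch sequence of a melody
#'
#' Maps a melody's scale degrees to MIDI pitches. Agrammatical variants are
#' rendered with the pitches of degrees 5 and 6 swapped; the degree content
#' itself is never altered, so applying [make_agrammatical_variant()] twice
#' restores the grammatical rendering.
#'
#' @param melody A `melody_record`.
#' @param mapping A `pitch_mapping`.
#' @return Integer vector of MIDI note numbers.
#' @export
melody_pitches <- function(melody, mapping) {
  stopifnot(inherits(melody, "melody_record"), inherits(mapping, "pitch_mapping"))
  d2p <- mapping$degree_to_pitch
  if (melody$variant == "agrammatical") {
    tmp <- d2p[["5"]]
    d2p[["5"]] <- d2p[["6"]]
    d2p[["6"]] <- tmp
  }
  unname(d2p[as.character(melody$degrees)])
}
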