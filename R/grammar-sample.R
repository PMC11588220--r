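#' Sample a degree sequence from one grammar cell
#'
#' Draws a sequence of scale degrees from a single cell of the grammar. The
#' first degree is drawn from the cell's initial distribution, restricted to
#' degrees that are legal after `entry_degree` (no repeat, step at most
#' `max_step`, no reserved context-target pair across the boundary);
#' subsequent degrees follow the cell's transition table. IC cells return
#' exactly `[context, target]`, with the high-probability target drawn with
#' probability `p_high`.
#'
#' @param spec A `grammar_spec`.
#' @param cell_name One of `"start"`, `"ic_alpha"`, `"intermediate"`,
#'   `"ic_beta"`, `"end"`.
#' @param entry_degree Scale degree of the note preceding this cell, or
#'   `NULL` at the start of a melody.
#' @param length_range Optional integer pair overriding the cell's length
#'   range (used by the shortened forced-choice grammar).
#'
#' @return An integer vector of scale degrees.
#' @seealso [generate_exposure_melody()], [generate_test_melody()]
#' @export
sample_cell <- function(spec, cell_name, entry_degree = NULL,
                        length_range = NULL) {
  cell <- spec$cells[[cell_name]]
  if (is.null(cell)) abort(sprintf("unknown cell '%s'", cell_name))
  lr <- length_range %||% cell$length_range
  len <- if (lr[1] == lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)

  first_w <- restrict_weights(cell$init, entry_degree, spec$max_step)
  if (sum(first_w) == 0)
    dead_end(cell_name, entry_degree,
             "no legal entry into cell after this degree")
  out <- integer(len)
  out[1] <- sample_one(DEGREES, prob = first_w)
  for (k in seq_len(len - 1L)) {
    row <- cell$trans[out[k], ]
    if (sum(row) == 0)
      dead_end(cell_name, out[k], "no legal continuation from this degree")
    out[k + 1L] <- sample_one(DEGREES, prob = row)
  }
  out
}

# Zero out initial-distribution entries that are illegal after `entry`.
restrict_weights <- function(w, entry, max_step) {
  if (is.null(entry)) return(w)
  legal <- DEGREES != entry &
    abs(DEGREES - entry) <= max_step &
    !is_reserved_pair(rep(entry, 7), DEGREES)
  w * legal
}

dead_end <- function(cell, degree, msg) {
  abort(
    sprintf("sampling dead-end in cell '%s' at degree %s: %s",
            cell, degree %||% "<none>", msg),
    class = "icmelody_dead_end",
    cell = cell, degree = degree
  )
}

new_melody_record <- function(degrees, cell_spans, targets, phase, variant,
                              seed_tag = NA_character_) {
  structure(
    list(degrees = as.integer(degrees), cell_spans = cell_spans,
         targets = targets, phase = phase, variant = variant,
         seed_tag = seed_tag),
    class = "melody_record"
  )
}

#' @export
print.melody_record <- function(x, ...) {
  cat(sprintf("<melody_record> %s/%s, %d notes\n", x$phase, x$variant,
              length(x$degrees)))
  cat("  degrees:", paste(x$degrees, collapse = " "), "\n")
  for (i in seq_len(nrow(x$targets)))
    cat(sprintf("  target @%d: %s IC, %s contour%s\n",
                x$targets$position[i], x$targets$ic_condition[i],
                x$targets$contour[i],
                if (x$targets$accented[i]) ", accented" else ""))
  invisible(x)
}

annotate_targets <- function(degrees, cell_spans, cells) {
  ic_rows <- which(grepl("^ic_", cell_spans$cell))
  pos <- cell_spans$start[ic_rows] + 1L   # target = second note of each IC cell
  specs <- lapply(cell_spans$cell[ic_rows], function(nm) cells[[nm]]$ic)
  tibble::new_tibble(list(
    position = pos,
    ic_condition = ifelse(
      degrees[pos] == vapply(specs, `[[`, integer(1), "high_prob_target"),
      "low", "high"),
    context_degree = vapply(specs, `[[`, integer(1), "context"),
    contour = classify_contour(degrees[pos - 1L], degrees[pos],
                               degrees[pos + 1L]),
    accented = rep(FALSE, length(pos))
  ), nrow = length(pos))
}

#' Generate one exposure melody
#'
#' Assembles a full exposure melody by sampling each cell in one of the two
#' admissible module orders (start, IC-alpha, intermediate, IC-beta, end, or
#' with the IC cells swapped), chosen uniformly at random. Constrained
#' sampling proceeds by rejection: a dead-end at any cell boundary discards
#' the partial melody and restarts, up to `spec$max_retries` attempts.
#'
#' @param spec A `grammar_spec` that passes [validate_grammar()].
#' @param min_length Optional minimum total length (used for the long
#'   melodies of hard attention trials, which reuse this grammar conditioned
#'   on length >= 12 by rejection).
#' @param phase Phase label stored on the record, default `"exposure"`.
#'
#' @return A `melody_record` with 9-14 degrees and exactly two annotated
#'   targets, one per IC cell, each with an independent IC-branch draw.
#' @examples
#' spec <- default_grammar()
#' set.seed(1)
#' generate_exposure_melody(spec)
#' @export
generate_exposure_melody <- function(spec, min_length = NULL,
                                     phase = "exposure") {
  for (attempt in seq_len(spec$max_retries)) {
    order <- spec$module_orders[[sample.int(2L, 1L)]]
    res <- try_melody(spec, order, length_overrides = list())
    if (is.null(res)) next
    if (!is.null(min_length) && length(res$degrees) < min_length) next
    targets <- annotate_targets(res$degrees, res$cell_spans, spec$cells)
    return(new_melody_record(res$degrees, res$cell_spans, targets,
                             phase = phase, variant = "grammatical"))
  }
  abort(sprintf("failed to generate an exposure melody in %d attempts",
                spec$max_retries),
        class = "icmelody_dead_end")
}

# Sample cells in order; NULL on dead-end so the caller can resample.
try_melody <- function(spec, order, length_overrides) {
  degrees <- integer(0)
  starts <- ends <- integer(length(order))
  for (i in seq_along(order)) {
    nm <- order[i]
    entry <- if (length(degrees)) degrees[length(degrees)] else NULL
    seq_i <- tryCatch(
      sample_cell(spec, nm, entry_degree = entry,
                  length_range = length_overrides[[nm]]),
      icmelody_dead_end = function(e) NULL
    )
    if (is.null(seq_i)) return(NULL)
    starts[i] <- length(degrees) + 1L
    ends[i] <- length(degrees) + length(seq_i)
    degrees <- c(degrees, seq_i)
  }
  list(degrees = degrees,
       cell_spans = tibble::new_tibble(
         list(cell = order, start = starts, end = ends),
         nrow = length(order)))
}

#' Generate one forced-choice test melody
#'
#' Test melodies use a shortened grammar: one IC cell (alpha or beta, chosen
#' uniformly unless fixed), no intermediate cell, a 2-3 note start cell and a
#' 3-4 note end cell, for a total of 7-9 notes with the single target near
#' the middle of the melody. The target branch is fixed by `ic_condition`
#' rather than drawn, and the first end-cell note is restricted to degrees
#' legal after *either* target branch, so that a matched variant with the
#' other IC condition and identical flanking notes always exists (see
#' [matched_variant()]).
#'
#' @param spec A `grammar_spec`.
#' @param ic_condition `"high"` or `"low"`: the surprisal of the target.
#' @param contour Optional contour class (`"peak"`, `"valley"`,
#'   `"ascending"`, `"descending"`) required at the target, achieved by
#'   rejection sampling.
#' @param ic_cell Optional `"ic_alpha"` or `"ic_beta"` to fix the IC cell.
#' @param max_tries Rejection-sampling cap, default 1000.
#'
#' @return A `melody_record` with `phase = "test"` and exactly one target.
#' @examples
#' spec <- default_grammar()
#' set.seed(7)
#' generate_test_melody(spec, "high")
#' @export
generate_test_melody <- function(spec, ic_condition = c("high", "low"),
                                 contour = NULL, ic_cell = NULL,
                                 max_tries = 1000L) {
  ic_condition <- match.arg(ic_condition)
  if (!is.null(contour)) {
    # the requested contour fixes the compatible IC cell: peak/ascending need
    # a context below the target, valley/descending a context above it
    rising <- contour %in% c("peak", "ascending")
    compatible <- Filter(function(nm) {
      ic <- spec$cells[[nm]]$ic
      tg <- if (ic_condition == "low") ic$high_prob_target else ic$low_prob_target
      (ic$context < tg) == rising
    }, c("ic_alpha", "ic_beta"))
    if (!is.null(ic_cell)) compatible <- intersect(compatible, ic_cell)
    if (length(compatible) == 0)
      abort(sprintf("no IC cell can realise a %s-IC %s target",
                    ic_condition, contour))
    ic_cell <- compatible
  }
  for (attempt in seq_len(max_tries)) {
    nm <- if (is.null(ic_cell)) sample(c("ic_alpha", "ic_beta"), 1L)
          else sample_one(ic_cell)
    cell <- spec$cells[[nm]]
    target <- if (ic_condition == "low") cell$ic$high_prob_target
              else cell$ic$low_prob_target
    other <- if (ic_condition == "low") cell$ic$low_prob_target
             else cell$ic$high_prob_target

    start_seq <- tryCatch(
      sample_cell(spec, "start", length_range = spec$test_cell_lengths$start),
      icmelody_dead_end = function(e) NULL
    )
    if (is.null(start_seq)) next
    prev <- start_seq[length(start_seq)]
    if (prev == cell$ic$context) next  # would repeat into the context

    # end-cell entry must be legal after both target branches so that the
    # matched variant shares every flanking note
    end_cell <- spec$cells$end
    w <- restrict_weights(end_cell$init, target, spec$max_step) *
         (restrict_weights(rep(1, 7), other, spec$max_step) > 0)
    if (!is.null(contour)) {
      # condition the entry on the contour class directly (equivalent to
      # rejection, since the contour depends only on this note)
      w <- w * if (contour %in% c("peak", "descending")) DEGREES < target
               else DEGREES > target
    }
    if (sum(w) == 0) next
    end_len_r <- spec$test_cell_lengths$end
    end_len <- sample(end_len_r[1]:end_len_r[2], 1L)
    end_seq <- integer(end_len)
    end_seq[1] <- sample_one(DEGREES, prob = w)
    bad <- FALSE
    for (k in seq_len(end_len - 1L)) {
      row <- end_cell$trans[end_seq[k], ]
      if (sum(row) == 0) { bad <- TRUE; break }
      end_seq[k + 1L] <- sample_one(DEGREES, prob = row)
    }
    if (bad) next

    degrees <- c(start_seq, cell$ic$context, target, end_seq)
    pos <- length(start_seq) + 2L
    ctr <- classify_contour(degrees[pos - 1L], degrees[pos], degrees[pos + 1L])
    if (!is.null(contour) && ctr != contour) next

    spans <- tibble::new_tibble(list(
      cell = c("start", nm, "end"),
      start = c(1L, length(start_seq) + 1L, pos + 1L),
      end = c(length(start_seq), pos, length(degrees))
    ), nrow = 3L)
    targets <- tibble::new_tibble(list(
      position = pos, ic_condition = ic_condition,
      context_degree = cell$ic$context, contour = ctr, accented = FALSE
    ), nrow = 1L)
    return(new_melody_record(degrees, spans, targets,
                             phase = "test", variant = "grammatical"))
  }
  abort(sprintf("failed to generate a test melody in %d attempts", max_tries),
        class = "icmelody_dead_end")
}

#' Matched forced-choice variant with the other IC condition
#'
#' Returns the melody that is identical to `melody` at every position except
#' the single target note, where the other IC branch of the same IC cell is
#' substituted (high-IC for low-IC or vice versa). The contour annotation is
#' recomputed for the new target.
#'
#' @param melody A test `melody_record` with exactly one target.
#' @return A `melody_record` differing from the input only at the target.
#' @export
matched_variant <- function(melody, spec = default_grammar()) {
  stopifnot(inherits(melody, "melody_record"))
  if (nrow(melody$targets) != 1L)
    abort("matched_variant() requires a forced-choice melody with one target")
  nm <- melody$cell_spans$cell[grepl("^ic_", melody$cell_spans$cell)]
  ic <- spec$cells[[nm]]$ic
  pos <- melody$targets$position
  cur <- melody$degrees[pos]
  new_target <- if (cur == ic$high_prob_target) ic$low_prob_target
                else ic$high_prob_target
  out <- melody
  out$degrees[pos] <- new_target
  out$targets$ic_condition <- if (new_target == ic$high_prob_target) "low" else "high"
  out$targets$contour <- classify_contour(out$degrees[pos - 1L],
                                          out$degrees[pos],
                                          out$degrees[pos + 1L])
  out
}

#' Classify the local melodic contour at a note
#'
#' A note's contour class is determined by its two neighbours: `peak` if
#' both the preceding and succeeding pitches are lower, `valley` if both are
#' higher, `ascending` if the preceding pitch is lower and the succeeding
#' higher, and `descending` if the preceding pitch is higher and the
#' succeeding lower. Vectorised over its arguments.
#'
#' @param prev,target,nxt Scale degrees (or any monotone pitch encoding) of
#'   the preceding, focal, and succeeding note.
#' @return A character vector in
#'   `c("peak", "valley", "ascending", "descending")`.
#' @examples
#' classify_contour(5, 6, 5)  # "peak"
#' classify_contour(5, 4, 5)  # "valley"
#' @export
classify_contour <- function(prev, target, nxt) {
  if (any(prev == target) || any(nxt == target))
    abort("contour undefined: adjacent notes are equal (repeats are banned)")
  out <- character(length(target))
  out[prev < target & nxt < target] <- "peak"
  out[prev > target & nxt > target] <- "valley"
  out[prev < target & nxt > target] <- "ascending"
  out[out == ""] <- "descending"
  out
}

#' Set or clear the dynamic accent on a target note
#'
#' Marks an annotated target note as accented. Only the accent flag changes;
#' the degree content is untouched. The rendering layer maps the flag to a
#' higher MIDI velocity. Applying with `accented = FALSE` restores the
#' original record, so accenting is an involution.
#'
#' @param melody A `melody_record`.
#' @param target_index Position (1-based, into `melody$degrees`) of an
#'   annotated target.
#' @param accented Logical flag to set. Default `TRUE`.
#' @return The modified `melody_record`.
#' @export
apply_accent <- function(melody, target_index, accented = TRUE) {
  stopifnot(inherits(melody, "melody_record"))
  hit <- melody$targets$position == target_index
  if (!any(hit))
    abort(sprintf("position %d is not an annotated target", target_index))
  melody$targets$accented[hit] <- accented
  melody
}

#' Toggle the agrammatical rendering of a melody
#'
#' Agrammatical melodies share the degree content of grammatical ones but are
#' rendered with the pitch assignment of scale degrees 5 and 6 inverted. This
#' function only flips the `variant` flag; the swap is applied by the pitch
#' mapping at render time. Applying twice restores grammatical rendering.
#'
#' @param melody A `melody_record`.
#' @return The record with `variant` toggled between `"grammatical"` and
#'   `"agrammatical"`.
#' @export
make_agrammatical_variant <- function(melody) {
  stopifnot(inherits(melody, "melody_record"))
  melody$variant <- if (melody$variant == "grammatical") "agrammatical"
                    else "grammatical"
  melody
}

#' Validate a melody record against the grammar's global constraints
#'
#' @param melody A `melody_record`.
#' @param spec The `grammar_spec` it was generated from.
#' @return A tibble of violations (`rule`, `detail`); zero rows if valid.
#' @export
validate_melody <- function(melody, spec = default_grammar()) {
  d <- melody$degrees
  v <- list()
  add <- function(rule, detail)
    v[[length(v) + 1L]] <<- tibble::tibble(rule = rule, detail = detail)

  if (any(d < 1L | d > 7L)) add("degree range", "degrees outside 1-7")
  if (any(diff(d) == 0L)) add("repeated note", "adjacent equal degrees")
  if (any(abs(diff(d)) > spec$max_step))
    add("step too large", sprintf("step exceeds %d degrees", spec$max_step))

  ic_spans <- melody$cell_spans[grepl("^ic_", melody$cell_spans$cell), ]
  ic_pos <- unlist(lapply(seq_len(nrow(ic_spans)), function(r)
    ic_spans$start[r]))  # index of the context->target transition
  for (k in seq_len(length(d) - 1L)) {
    if (is_reserved_pair(d[k], d[k + 1L]) && !(k %in% ic_pos))
      add("reserved pair outside IC cell",
          sprintf("pair %d->%d at position %d", d[k], d[k + 1L], k))
  }

  lb <- if (melody$phase == "test") spec$test_length else spec$exposure_length
  if (length(d) < lb[1] || length(d) > lb[2])
    add("length bounds", sprintf("length %d outside [%d, %d]",
                                 length(d), lb[1], lb[2]))

  n_expected <- if (melody$phase == "test") 1L else 2L
  if (nrow(melody$targets) != n_expected)
    add("target count", sprintf("%d targets, expected %d",
                                nrow(melody$targets), n_expected))
  for (r in seq_len(nrow(melody$targets))) {
    p <- melody$targets$position[r]
    if (p <= 1L || p >= length(d))
      add("target position", "target is first or last note")
    else {
      if (d[p - 1L] != melody$targets$context_degree[r])
        add("target adjacency", "target not preceded by its context degree")
      if (abs(d[p] - d[p - 1L]) != 1L)
        add("target adjacency", "context-target interval is not one degree")
    }
  }
  if (length(v) == 0) tibble::tibble(rule = character(), detail = character())
  else dplyr::bind_rows(v)
}

#' Generate a corpus of melodies as a tibble
#'
#' Generates `n` melodies with per-melody derived RNG substreams, so any
#' individual melody can be regenerated bit-exactly from its `seed_tag`
#' (`"<master seed>-<melody index>"`).
#'
#' @param spec A `grammar_spec`.
#' @param n Number of melodies.
#' @param kind `"exposure"` or `"test"`.
#' @param seed Optional master seed; per-melody substreams are derived from
#'   it. `NULL` uses the current RNG state.
#' @param ic_conditions For `kind = "test"`: recycled vector of `"high"` /
#'   `"low"` target conditions (default alternating).
#'
#' @return A tibble with one row per melody: `melody_id`, `seed_tag`,
#'   `phase`, `variant`, `length`, and list-columns `degrees`, `targets`,
#'   `cell_spans`.
#' @examples
#' corpus <- generate_corpus(default_grammar(), 20, seed = 1)
#' dplyr::count(corpus, length)
#' @export
generate_corpus <- function(spec, n, kind = c("exposure", "test"), seed = NULL,
                            ic_conditions = NULL) {
  kind <- match.arg(kind)
  if (kind == "test" && is.null(ic_conditions))
    ic_conditions <- rep(c("high", "low"), length.out = n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- if (is.null(seed)) NULL else derive_seed(seed, i)
    rec <- with_seed(sub, {
      if (kind == "exposure") generate_exposure_melody(spec)
      else generate_test_melody(spec, ic_conditions[[i]])
    })
    rec$seed_tag <- if (is.null(seed)) NA_character_
                    else sprintf("%d-%d", seed, i)
    recs[[i]] <- rec
  }
  tibble::tibble(
    melody_id = sprintf("%s_%05d", kind, seq_len(n)),
    seed_tag = vapply(recs, `[[`, character(1), "seed_tag"),
    phase = vapply(recs, `[[`, character(1), "phase"),
    variant = vapply(recs, `[[`, character(1), "variant"),
    length = vapply(recs, function(r) length(r$degrees), integer(1)),
    degrees = lapply(recs, `[[`, "degrees"),
    targets = lapply(recs, `[[`, "targets"),
    cell_spans = lapply(recs, `[[`, "cell_spans")
  )
}

#' Rebuild a melody_record from a corpus row
#'
#' @param corpus A tibble from [generate_corpus()].
#' @param i Row index.
#' @return A `melody_record`.
#' @export
corpus_record <- function(corpus, i) {
  new_melody_record(corpus$degrees[[i]], corpus$cell_spans[[i]],
                    corpus$targets[[i]], corpus$phase[i], corpus$variant[i],
                    corpus$seed_tag[i])
}
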