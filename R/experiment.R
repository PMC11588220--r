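#' @name experiment_builder
#' @title Building the experiment protocol
#' @description
#' The full protocol has four phases. Exposure: 45 passive trials of 4
#' melodies each (180 exposure melodies in total), with active trials
#' (attention and liking) randomly interleaved at an average rate of one per
#' two passive trials. Grammar-learning test: 16 melodies, 8 grammatical and
#' 8 agrammatical (degrees 5/6 pitch-swapped), in random order, each rated
#' for similarity to the exposure set. Two forced-choice tests of 16 items
#' each: the accent-preference test (identical melodies, accented vs plain
#' target; half high-IC, half low-IC) and the IC-preference test (matched
#' melodies differing only at the target, high- vs low-IC; half with both
#' members accented, half with neither).
NULL

new_schedule <- function(trials, stimuli, seed = NA_integer_) {
  structure(list(trials = trials, stimuli = stimuli, seed = seed),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat("<trial_schedule>", nrow(x$trials), "trials,", length(x$stimuli),
      "stimuli\n")
  print(dplyr::count(x$trials, .data$phase, .data$kind))
  invisible(x)
}

trial_row <- function(phase, kind, stimulus_ids, ...) {
  extra <- list(...)
  defaults <- list(difficulty = NA_character_, correct_answer = NA_character_,
                   variant = NA_character_, ic_condition = NA_character_,
                   contour = NA_character_, accent_arm = NA_character_,
                   presentation_order = NA_character_)
  defaults[names(extra)] <- extra
  tibble::new_tibble(c(list(phase = phase, kind = kind,
                            stimulus_ids = list(stimulus_ids)), defaults),
                     nrow = 1L)
}

stim_id <- function(prefix, i) sprintf("%s_%03d", prefix, i)

#' Build the exposure-phase schedule
#'
#' 45 passive trials of four exposure melodies each, with active trials
#' interleaved at random positions: never the first trial of the phase and
#' never two in a row. Active trials split 2:1 between attention trials
#' (identify the shorter of two melodies; difficulties easy 7 vs 14,
#' intermediate 7 vs 9, hard 12 vs 14 notes, with long melodies from the
#' exposure grammar and short ones from the forced-choice grammar) and
#' liking trials (rate one exposure melody).
#'
#' @param spec A `grammar_spec`.
#' @param seed Optional seed for reproducible builds.
#' @param n_passive Number of passive trials. Default 45.
#' @param melodies_per_passive Melodies per passive trial. Default 4.
#' @param active_rate Average active trials per passive trial. Default 0.5.
#' @param liking_share Fraction of active trials that are liking trials.
#'   Default 1/3.
#' @return A `trial_schedule` for the exposure phase.
#' @export
build_exposure_schedule <- function(spec, seed = NULL, n_passive = 45L,
                                    melodies_per_passive = 4L,
                                    active_rate = 0.5, liking_share = 1 / 3) {
  with_seed(seed, {
    stimuli <- list()
    trials <- list()

    n_active <- as.integer(floor(n_passive * active_rate))
    n_liking <- as.integer(round(n_active * liking_share))
    n_attention <- n_active - n_liking

    passive <- vector("list", n_passive)
    for (i in seq_len(n_passive)) {
      ids <- character(melodies_per_passive)
      for (j in seq_len(melodies_per_passive)) {
        id <- stim_id("exp", (i - 1L) * melodies_per_passive + j)
        stimuli[[id]] <- generate_exposure_melody(spec)
        ids[j] <- id
      }
      passive[[i]] <- trial_row("exposure", "passive", ids)
    }

    diffs <- sample(rep(c("easy", "intermediate", "hard"),
                        length.out = n_attention))
    att_lengths <- list(easy = c(7L, 14L), intermediate = c(7L, 9L),
                        hard = c(12L, 14L))
    active <- vector("list", n_active)
    for (i in seq_len(n_attention)) {
      lens <- att_lengths[[diffs[i]]]
      pair <- lapply(lens, function(L) {
        if (L >= spec$exposure_length[1])
          melody_of_length(spec, L, kind = "exposure")
        else melody_of_length(spec, L, kind = "test")
      })
      order2 <- sample.int(2L)
      ids <- c(stim_id("att", 2L * i - 1L), stim_id("att", 2L * i))
      stimuli[[ids[1]]] <- pair[[order2[1]]]
      stimuli[[ids[2]]] <- pair[[order2[2]]]
      active[[i]] <- trial_row(
        "exposure", "attention", ids, difficulty = diffs[i],
        correct_answer = ids[which(lens[order2] == min(lens))]
      )
    }
    for (i in seq_len(n_liking)) {
      id <- stim_id("lik", i)
      stimuli[[id]] <- generate_exposure_melody(spec)
      active[[n_attention + i]] <- trial_row("exposure", "liking", id)
    }
    active <- active[sample.int(n_active)]

    slots <- place_active(n_passive, n_active)
    merged <- vector("list", n_passive + n_active)
    merged[slots] <- active
    merged[setdiff(seq_along(merged), slots)] <- passive
    trials <- dplyr::bind_rows(merged)
    trials$trial_index <- seq_len(nrow(trials))
    new_schedule(dplyr::relocate(trials, "trial_index"), stimuli,
                 seed %||% NA_integer_)
  })
}

# Positions for active trials among n_passive + n_active slots: never slot 1,
# never adjacent. Sampled uniformly by thinning.
place_active <- function(n_passive, n_active) {
  n_slots <- n_passive + n_active
  repeat {
    cand <- sort(sample(2:n_slots, n_active))
    if (n_active < 2L || all(diff(cand) > 1L)) return(cand)
  }
}

# Exact-length melody via rejection; lengths within either grammar's support.
melody_of_length <- function(spec, L, kind, max_tries = 5000L) {
  for (i in seq_len(max_tries)) {
    m <- if (kind == "exposure")
      generate_exposure_melody(spec, phase = "attention_long")
    else generate_test_melody(spec, sample(c("high", "low"), 1L))
    if (length(m$degrees) == L) return(m)
  }
  abort(sprintf("could not generate a %d-note melody in %d tries",
                L, max_tries))
}

#' Build the grammar-learning test
#'
#' 16 trials in random order: 8 grammatical melodies drawn from the exposure
#' grammar and 8 agrammatical ones (same construction, degrees 5 and 6
#' pitch-swapped at rendering via [make_agrammatical_variant()]).
#'
#' @inheritParams build_exposure_schedule
#' @param n_each Melodies per variant. Default 8.
#' @return A `trial_schedule` for the learning phase.
#' @export
build_learning_test <- function(spec, seed = NULL, n_each = 8L) {
  with_seed(seed, {
    stimuli <- list()
    trials <- vector("list", 2L * n_each)
    for (i in seq_len(2L * n_each)) {
      m <- generate_exposure_melody(spec)
      variant <- if (i <= n_each) "grammatical" else "agrammatical"
      if (variant == "agrammatical") m <- make_agrammatical_variant(m)
      id <- stim_id("learn", i)
      stimuli[[id]] <- m
      trials[[i]] <- trial_row("learning", "learning", id, variant = variant)
    }
    trials <- dplyr::bind_rows(trials[sample.int(2L * n_each)])
    trials$trial_index <- seq_len(nrow(trials))
    trials$item_id <- sprintf("learn_item_%02d", seq_len(nrow(trials)))
    new_schedule(dplyr::relocate(trials, "trial_index"), stimuli,
                 seed %||% NA_integer_)
  })
}

# The 16-item contour x condition design shared by both forced-choice tests:
# each contour class appears 4 times, crossed evenly with the second factor.
fc_design <- function(second_levels) {
  tidyr::expand_grid(
    contour = c("peak", "valley", "ascending", "descending"),
    second = second_levels,
    rep = 1:2
  )
}

#' Build the accent-preference forced-choice test
#'
#' 16 items, each presenting the same melody twice: once with the target
#' note accented and once plain, in randomised order. Eight items have a
#' high-IC target and eight a low-IC target, and each of the four contour
#' classes occurs four times (twice per IC condition), so contour and IC are
#' crossed and all contours are represented.
#'
#' @inheritParams build_exposure_schedule
#' @return A `trial_schedule` with `kind = "fc_accent"` trials; the
#'   `correct_answer` column holds the id of the accented member.
#' @export
build_accent_preference_test <- function(spec, seed = NULL) {
  with_seed(seed, {
    design <- fc_design(c("high", "low"))
    design <- design[sample.int(nrow(design)), ]
    stimuli <- list()
    trials <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      m <- generate_test_melody(spec, design$second[i],
                                contour = design$contour[i])
      acc <- apply_accent(m, m$targets$position)
      ids <- c(stim_id("fca_acc", i), stim_id("fca_pla", i))
      stimuli[[ids[1]]] <- acc
      stimuli[[ids[2]]] <- m
      ord <- sample.int(2L)
      trials[[i]] <- trial_row(
        "fc_accent", "fc_accent", ids[ord],
        ic_condition = design$second[i], contour = design$contour[i],
        correct_answer = ids[1],
        presentation_order = if (ord[1] == 1L) "accented_first" else "plain_first"
      )
    }
    trials <- dplyr::bind_rows(trials)
    trials$trial_index <- seq_len(nrow(trials))
    trials$item_id <- sprintf("fca_item_%02d", seq_len(nrow(trials)))
    new_schedule(dplyr::relocate(trials, "trial_index"), stimuli,
                 seed %||% NA_integer_)
  })
}

#' Build the IC-preference forced-choice test
#'
#' 16 items, each presenting two matched melodies that differ only at the
#' target note: one high-IC, one low-IC (the other branch of the same IC
#' cell, identical flanking notes). In eight items both members are
#' accented, in eight neither. The contour of the high-IC member covers all
#' four classes, crossed evenly with the accent arm.
#'
#' @inheritParams build_exposure_schedule
#' @return A `trial_schedule` with `kind = "fc_ic"` trials; the
#'   `correct_answer` column holds the id of the high-IC member.
#' @export
build_ic_preference_test <- function(spec, seed = NULL) {
  with_seed(seed, {
    design <- fc_design(c("accented", "plain"))
    design <- design[sample.int(nrow(design)), ]
    stimuli <- list()
    trials <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      high <- generate_test_melody(spec, "high", contour = design$contour[i])
      low <- matched_variant(high, spec)
      if (design$second[i] == "accented") {
        high <- apply_accent(high, high$targets$position)
        low <- apply_accent(low, low$targets$position)
      }
      ids <- c(stim_id("fci_high", i), stim_id("fci_low", i))
      stimuli[[ids[1]]] <- high
      stimuli[[ids[2]]] <- low
      ord <- sample.int(2L)
      trials[[i]] <- trial_row(
        "fc_ic", "fc_ic", ids[ord],
        accent_arm = design$second[i], contour = design$contour[i],
        correct_answer = ids[1],
        presentation_order = if (ord[1] == 1L) "high_first" else "low_first"
      )
    }
    trials <- dplyr::bind_rows(trials)
    trials$trial_index <- seq_len(nrow(trials))
    trials$item_id <- sprintf("fci_item_%02d", seq_len(nrow(trials)))
    new_schedule(dplyr::relocate(trials, "trial_index"), stimuli,
                 seed %||% NA_integer_)
  })
}

#' Build the full experiment for one participant/tonic condition
#'
#' Concatenates the exposure phase, the grammar-learning test and the two
#' forced-choice tests (the order of the two forced-choice tests is
#' randomised, as in the protocol).
#'
#' @inheritParams build_exposure_schedule
#' @param tonic_index Tonic listening condition, 0-5 (window position of the
#'   pitch mapping; stored on the schedule, applied at render time).
#' @return A `trial_schedule` with an added `tonic_index` element.
#' @export
build_experiment <- function(spec, tonic_index = 0L, seed = NULL) {
  with_seed(seed, {
    parts <- list(
      build_exposure_schedule(spec),
      build_learning_test(spec)
    )
    fc <- list(build_accent_preference_test(spec),
               build_ic_preference_test(spec))
    parts <- c(parts, fc[sample.int(2L)])
    trials <- dplyr::bind_rows(lapply(parts, function(p) p$trials))
    trials$trial_index <- seq_len(nrow(trials))
    stimuli <- do.call(c, lapply(parts, function(p) p$stimuli))
    sched <- new_schedule(trials, stimuli, seed %||% NA_integer_)
    sched$tonic_index <- as.integer(tonic_index)
    sched
  })
}

#' Render every stimulus of a schedule to MIDI files
#'
#' @param schedule A `trial_schedule`.
#' @param mapping A `pitch_mapping`.
#' @param dir Output directory (created if needed).
#' @param cfg A [render_config()].
#' @return Invisibly, a tibble with `stimulus_id` and `path`.
#' @export
render_schedule_midi <- function(schedule, mapping, dir,
                                 cfg = render_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(schedule$stimuli)
  paths <- file.path(dir, paste0(ids, ".mid"))
  for (i in seq_along(ids))
    write_melody_midi(schedule$stimuli[[ids[i]]], mapping, paths[i], cfg)
  invisible(tibble::tibble(stimulus_id = ids, path = paths))
}

#' Serialize / restore a trial schedule
#'
#' Writes a JSON-lines manifest, one trial per line, with each referenced
#' stimulus embedded (degrees, cell spans with 0-based indices, targets with
#' 0-based positions, phase, variant), so the file is self-contained and the
#' round trip is lossless.
#'
#' @param schedule A `trial_schedule`.
#' @param path Output file.
#' @return `write_schedule_manifest()`: `path`, invisibly.
#'   `read_schedule_manifest()`: the restored `trial_schedule`.
#' @export
write_schedule_manifest <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(type = "schedule_meta", seed = schedule$seed,
               tonic_index = schedule$tonic_index %||% NA_integer_)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, na = "null"), con)
  for (i in seq_len(nrow(schedule$trials))) {
    tr <- schedule$trials[i, ]
    stim <- lapply(tr$stimulus_ids[[1]], function(id) {
      m <- schedule$stimuli[[id]]
      list(id = id, degrees = m$degrees,
           phase = m$phase, variant = m$variant, seed_tag = m$seed_tag,
           cell_spans = lapply(seq_len(nrow(m$cell_spans)), function(r)
             list(cell = m$cell_spans$cell[r],
                  start = m$cell_spans$start[r] - 1L,
                  end = m$cell_spans$end[r] - 1L)),
           targets = lapply(seq_len(nrow(m$targets)), function(r)
             list(position = m$targets$position[r] - 1L,
                  ic_condition = m$targets$ic_condition[r],
                  context_degree = m$targets$context_degree[r],
                  contour = m$targets$contour[r],
                  accented = m$targets$accented[r])))
    })
    line <- list(type = "trial",
                 trial_index = tr$trial_index, phase = tr$phase,
                 kind = tr$kind, difficulty = tr$difficulty,
                 correct_answer = tr$correct_answer, variant = tr$variant,
                 ic_condition = tr$ic_condition, contour = tr$contour,
                 accent_arm = tr$accent_arm,
                 presentation_order = tr$presentation_order,
                 item_id = if ("item_id" %in% names(tr)) tr$item_id else NA,
                 stimuli = stim)
    writeLines(jsonlite::toJSON(line, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_schedule_manifest
#' @export
read_schedule_manifest <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  stimuli <- list()
  trials <- vector("list", length(lines) - 1L)
  for (i in seq_along(trials)) {
    tr <- jsonlite::fromJSON(lines[i + 1L], simplifyDataFrame = FALSE)
    ids <- character(length(tr$stimuli))
    for (k in seq_along(tr$stimuli)) {
      s <- tr$stimuli[[k]]
      ids[k] <- s$id
      if (is.null(stimuli[[s$id]])) {
        spans <- dplyr::bind_rows(lapply(s$cell_spans, function(cs)
          tibble::tibble(cell = cs$cell, start = cs$start + 1L,
                         end = cs$end + 1L)))
        tg <- dplyr::bind_rows(lapply(s$targets, function(t)
          tibble::tibble(position = t$position + 1L,
                         ic_condition = t$ic_condition,
                         context_degree = t$context_degree,
                         contour = t$contour, accented = t$accented)))
        stimuli[[s$id]] <- new_melody_record(
          unlist(s$degrees), spans, tg, s$phase, s$variant,
          s$seed_tag %||% NA_character_)
      }
    }
    trials[[i]] <- trial_row(tr$phase, tr$kind, ids,
                             difficulty = tr$difficulty %||% NA_character_,
                             correct_answer = tr$correct_answer %||% NA_character_,
                             variant = tr$variant %||% NA_character_,
                             ic_condition = tr$ic_condition %||% NA_character_,
                             contour = tr$contour %||% NA_character_,
                             accent_arm = tr$accent_arm %||% NA_character_,
                             presentation_order =
                               tr$presentation_order %||% NA_character_)
    trials[[i]]$trial_index <- tr$trial_index
    trials[[i]]$item_id <- tr$item_id %||% NA_character_
  }
  trials <- dplyr::bind_rows(trials)
  sched <- new_schedule(dplyr::relocate(trials, "trial_index"), stimuli,
                        meta$seed %||% NA_integer_)
  if (!is.null(meta$tonic_index) && !is.na(meta$tonic_index))
    sched$tonic_index <- meta$tonic_index
  sched
}
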