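test_that("exposure phase counts match the protocol", {
  sched <- build_exposure_schedule(default_spec, seed = 1)
  tr <- sched$trials
  passive <- dplyr::filter(tr, .data$kind == "passive")
  expect_identical(nrow(passive), 45L)
  expect_identical(sum(lengths(passive$stimulus_ids)), 180L)
  n_active <- sum(tr$kind %in% c("attention", "liking"))
  expect_identical(n_active, 22L)  # floor(45 / 2): one active per two passive
  # never first, never adjacent
  active_pos <- which(tr$kind != "passive")
  expect_gt(min(active_pos), 1L)
  expect_true(all(diff(active_pos) > 1L))
})

test_that("attention trials pair the advertised lengths", {
  sched <- build_exposure_schedule(default_spec, seed = 2)
  att <- dplyr::filter(sched$trials, .data$kind == "attention")
  want <- list(easy = c(7L, 14L), intermediate = c(7L, 9L),
               hard = c(12L, 14L))
  for (i in seq_len(nrow(att))) {
    lens <- vapply(att$stimulus_ids[[i]],
                   function(id) length(sched$stimuli[[id]]$degrees),
                   integer(1))
    expect_identical(sort(unname(lens)), want[[att$difficulty[i]]])
    shorter <- att$stimulus_ids[[i]][which.min(lens)]
    expect_identical(att$correct_answer[i], unname(shorter))
  }
})

test_that("learning test is 8 grammatical + 8 agrammatical in random order", {
  sched <- build_learning_test(default_spec, seed = 3)
  expect_identical(nrow(sched$trials), 16L)
  expect_identical(sum(sched$trials$variant == "grammatical"), 8L)
  expect_identical(sum(sched$trials$variant == "agrammatical"), 8L)
  ag_ids <- unlist(
    sched$trials$stimulus_ids[sched$trials$variant == "agrammatical"])
  for (id in ag_ids)
    expect_identical(sched$stimuli[[id]]$variant, "agrammatical")
})

test_that("accent-preference test crosses IC and contour over 16 items", {
  sched <- build_accent_preference_test(default_spec, seed = 4)
  tr <- sched$trials
  expect_identical(nrow(tr), 16L)
  expect_identical(sum(tr$ic_condition == "high"), 8L)
  expect_identical(sort(unique(tr$contour)),
                   c("ascending", "descending", "peak", "valley"))
  expect_true(all(table(tr$contour) == 4L))
  for (i in seq_len(nrow(tr))) {
    pair <- lapply(tr$stimulus_ids[[i]], function(id) sched$stimuli[[id]])
    expect_identical(pair[[1]]$degrees, pair[[2]]$degrees)
    expect_identical(sum(pair[[1]]$targets$accented,
                         pair[[2]]$targets$accented), 1L)
    acc <- pair[[which(c(pair[[1]]$targets$accented,
                         pair[[2]]$targets$accented))]]
    expect_identical(acc$targets$ic_condition, tr$ic_condition[i])
    expect_identical(acc$targets$contour, tr$contour[i])
  }
})

test_that("IC-preference test pairs matched variants with accent arms", {
  sched <- build_ic_preference_test(default_spec, seed = 5)
  tr <- sched$trials
  expect_identical(nrow(tr), 16L)
  expect_identical(sum(tr$accent_arm == "accented"), 8L)
  expect_identical(sort(unique(tr$contour)),
                   c("ascending", "descending", "peak", "valley"))
  for (i in seq_len(nrow(tr))) {
    pair <- lapply(tr$stimulus_ids[[i]], function(id) sched$stimuli[[id]])
    conds <- vapply(pair, function(p) p$targets$ic_condition, character(1))
    expect_setequal(conds, c("high", "low"))
    d1 <- pair[[1]]$degrees; d2 <- pair[[2]]$degrees
    expect_identical(length(d1), length(d2))
    expect_identical(sum(d1 != d2), 1L)
    expect_identical(which(d1 != d2), pair[[1]]$targets$position)
    both_acc <- vapply(pair, function(p) p$targets$accented, logical(1))
    expect_identical(unique(both_acc), tr$accent_arm[i] == "accented")
  }
})

test_that("schedule builds are deterministic given a seed", {
  a <- build_experiment(default_spec, tonic_index = 1, seed = 11)
  b <- build_experiment(default_spec, tonic_index = 1, seed = 11)
  expect_identical(a$trials, b$trials)
  expect_identical(a$stimuli, b$stimuli)
})

test_that("a full experiment has every phase and resolvable stimuli", {
  sched <- build_experiment(default_spec, tonic_index = 2, seed = 12)
  counts <- dplyr::count(sched$trials, .data$phase)
  expect_setequal(counts$phase, c("exposure", "learning", "fc_accent", "fc_ic"))
  all_ids <- unique(unlist(sched$trials$stimulus_ids))
  expect_true(all(all_ids %in% names(sched$stimuli)))
  # every stimulus renders to a parseable MIDI file
  mapping <- build_pitch_mapping(hexascale(), sched$tonic_index)
  dir <- withr::local_tempdir()
  manifest <- render_schedule_midi(sched, mapping, dir)
  expect_true(all(file.exists(manifest$path)))
  one <- sched$stimuli[[manifest$stimulus_id[1]]]
  expect_identical(read_midi_notes(manifest$path[1])$pitch,
                   melody_pitches(one, mapping))
})

test_that("manifests round-trip losslessly", {
  sched <- build_experiment(default_spec, tonic_index = 3, seed = 13)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_schedule_manifest(sched, path)
  back <- read_schedule_manifest(path)
  cols <- c("trial_index", "phase", "kind", "difficulty", "correct_answer",
            "variant", "ic_condition", "contour", "accent_arm",
            "presentation_order")
  expect_identical(as.data.frame(back$trials[cols]),
                   as.data.frame(sched$trials[cols]))
  expect_identical(back$trials$stimulus_ids, sched$trials$stimulus_ids)
  expect_setequal(names(back$stimuli), names(sched$stimuli))
  for (id in names(sched$stimuli)) {
    expect_identical(back$stimuli[[id]]$degrees, sched$stimuli[[id]]$degrees)
    expect_identical(back$stimuli[[id]]$variant, sched$stimuli[[id]]$variant)
    expect_equal(back$stimuli[[id]]$targets, sched$stimuli[[id]]$targets)
  }
  expect_identical(back$tonic_index, sched$tonic_index)
})
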