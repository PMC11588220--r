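test_that("IC cells emit context then target, by branch probability", {
  # force each branch by pinning p_high, which fixes the drawn target
  forced_low <- default_grammar(p_high = 1)
  set.seed(1)
  expect_identical(sample_cell(forced_low, "ic_beta"), c(5L, 4L))
  expect_identical(sample_cell(forced_low, "ic_alpha"), c(3L, 4L))
  forced_high <- default_grammar(p_high = 0)
  expect_identical(sample_cell(forced_high, "ic_alpha"), c(3L, 2L))
  expect_identical(sample_cell(forced_high, "ic_beta"), c(5L, 6L))
})

test_that("within-cell high-probability branch rate matches the binomial law", {
  set.seed(101)
  n <- 10000
  for (cell in c("ic_alpha", "ic_beta")) {
    hits <- replicate(n, sample_cell(default_spec, cell)[2] == 4L)
    se <- sqrt(0.95 * 0.05 / n)
    expect_lt(abs(mean(hits) - 0.95), 3 * se)
  }
})

test_that("dead-ends raise a named sampling error", {
  stuck <- default_grammar()
  # a start cell that can only begin on degree 2 cannot be entered after 2
  stuck$cells$start$init <- setNames(c(0, 1, 0, 0, 0, 0, 0), 1:7)
  err <- expect_error(
    sample_cell(stuck, "start", entry_degree = 2L),
    class = "icmelody_dead_end"
  )
  expect_match(conditionMessage(err), "degree 2")
})

test_that("exposure melodies satisfy every structural invariant", {
  set.seed(11)
  for (i in 1:300) {
    m <- generate_exposure_melody(default_spec)
    expect_identical(nrow(validate_melody(m, default_spec)), 0L)
    expect_identical(nrow(m$targets), 2L)
  }
})

test_that("both module orders occur about equally often", {
  set.seed(21)
  first_ic <- replicate(2000, {
    m <- generate_exposure_melody(default_spec)
    m$cell_spans$cell[2]
  })
  p_alpha <- mean(first_ic == "ic_alpha")
  expect_lt(abs(p_alpha - 0.5), 3 * sqrt(0.25 / 2000))
  expect_setequal(unique(first_ic), c("ic_alpha", "ic_beta"))
})

test_that("test melodies are short, single-target, mid-melody", {
  set.seed(31)
  for (i in 1:200) {
    cond <- sample(c("high", "low"), 1)
    m <- generate_test_melody(default_spec, cond)
    expect_identical(nrow(validate_melody(m, default_spec)), 0L)
    expect_identical(m$targets$ic_condition, cond)
    L <- length(m$degrees)
    expect_gte(L, 7L); expect_lte(L, 9L)
    pos <- m$targets$position
    # target inside the middle third of the melody
    expect_gte(pos, ceiling(L / 3) + 1L)
    expect_lte(pos, ceiling(2 * L / 3))
  }
})

test_that("matched variants differ at exactly the target position", {
  set.seed(41)
  for (i in 1:100) {
    hi <- generate_test_melody(default_spec, "high")
    lo <- matched_variant(hi, default_spec)
    diffs <- which(hi$degrees != lo$degrees)
    expect_identical(diffs, hi$targets$position)
    expect_identical(lo$targets$ic_condition, "low")
    expect_identical(nrow(validate_melody(lo, default_spec)), 0L)
    # round trip restores the original
    expect_identical(matched_variant(lo, default_spec)$degrees, hi$degrees)
  }
})

test_that("contour-targeted generation realises every contour x IC cell", {
  set.seed(51)
  for (ctr in c("peak", "valley", "ascending", "descending"))
    for (cond in c("high", "low")) {
      m <- generate_test_melody(default_spec, cond, contour = ctr)
      expect_identical(m$targets$contour, ctr)
      expect_identical(m$targets$ic_condition, cond)
    }
})

test_that("accent flag is an involution restricted to targets", {
  set.seed(61)
  m <- generate_exposure_melody(default_spec)
  pos <- m$targets$position[1]
  acc <- apply_accent(m, pos)
  expect_true(acc$targets$accented[1])
  expect_identical(acc$degrees, m$degrees)
  expect_identical(apply_accent(acc, pos, accented = FALSE), m)
  non_target <- setdiff(seq_along(m$degrees), m$targets$position)[1]
  expect_error(apply_accent(m, non_target), "not an annotated target")
})

test_that("agrammatical conversion toggles rendering only", {
  set.seed(71)
  m <- generate_exposure_melody(default_spec)
  ag <- make_agrammatical_variant(m)
  expect_identical(ag$variant, "agrammatical")
  expect_identical(ag$degrees, m$degrees)
  expect_identical(make_agrammatical_variant(ag), m)
})

test_that("corpus generation is seed-tagged and reproducible", {
  c1 <- generate_corpus(default_spec, 10, seed = 99)
  c2 <- generate_corpus(default_spec, 10, seed = 99)
  expect_identical(c1, c2)
  expect_identical(c1$seed_tag[3], "99-3")
  # a single melody regenerates bit-exactly from its substream
  rec <- corpus_record(c1, 3)
  expect_identical(c1$degrees[[3]], rec$degrees)
})
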