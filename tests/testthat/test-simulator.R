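mk_profile <- function(u = 0, musician = FALSE)
  tibble::tibble(participant_id = "p001", musician = musician, u = u)

mk_item <- function(kind = "fc_accent", ic = "low", contour = "descending",
                    arm = NA_character_)
  tibble::tibble(kind = kind, item_id = "i1", ic_condition = ic,
                 contour = contour, accent_arm = arm,
                 presentation_order = "accented_first")

test_that("ratings follow the additive model exactly when noise is zero", {
  cfg <- sim_config(delta = 0, rating_noise = 0, rating_base = 4)
  trial_g <- tibble::tibble(kind = "learning", variant = "grammatical")
  trial_a <- tibble::tibble(kind = "learning", variant = "agrammatical")
  expect_identical(simulate_similarity_rating(mk_profile(), trial_g, cfg), 4L)
  expect_identical(simulate_similarity_rating(mk_profile(), trial_a, cfg), 4L)

  cfg2 <- sim_config(delta = 2, rating_noise = 0, rating_base = 3)
  g <- simulate_similarity_rating(mk_profile(), trial_g, cfg2)
  a <- simulate_similarity_rating(mk_profile(), trial_a, cfg2)
  expect_identical(g - a, 2L)
  expect_error(simulate_similarity_rating(mk_profile(), mk_item(), cfg2),
               "learning trial")
})

test_that("ratings are clamped to the 1-7 scale", {
  cfg <- sim_config(delta = 3, rating_noise = 0, rating_base = 6)
  trial_g <- tibble::tibble(kind = "learning", variant = "grammatical")
  expect_identical(simulate_similarity_rating(mk_profile(u = 5), trial_g, cfg),
                   7L)
  cfg2 <- sim_config(delta = 0, rating_noise = 0, rating_base = 1)
  trial_a <- tibble::tibble(kind = "learning", variant = "agrammatical")
  expect_identical(
    simulate_similarity_rating(mk_profile(u = -5), trial_a, cfg2), 1L)
})

test_that("all-zero coefficients give choice probability exactly one half", {
  cfg <- sim_config(beta_peak = 0, sigma_u = 0)
  set.seed(1)
  rec <- simulate_forced_choice(mk_profile(), mk_item(contour = "peak"), cfg)
  expect_identical(rec$p, 0.5)
  rec2 <- simulate_forced_choice(mk_profile(), mk_item("fc_ic", arm = "plain"),
                                 cfg)
  expect_identical(rec2$p, 0.5)
  expect_error(
    simulate_forced_choice(mk_profile(),
                           tibble::tibble(kind = "learning", item_id = "x",
                                          ic_condition = NA, contour = NA,
                                          accent_arm = NA,
                                          presentation_order = NA),
                           cfg),
    "not a forced-choice")
})

test_that("an overwhelming peak coefficient saturates peak items only", {
  cfg <- sim_config(beta_peak = 50, sigma_u = 0)
  set.seed(2)
  on_peak <- replicate(50, simulate_forced_choice(
    mk_profile(), mk_item(contour = "peak"), cfg)$choice)
  expect_true(all(on_peak == 1L))
  off_peak <- simulate_forced_choice(mk_profile(),
                                     mk_item(contour = "valley"), cfg)
  expect_identical(off_peak$p, 0.5)
})

test_that("Monte-Carlo choice rates match the logistic expectation", {
  cfg <- sim_config(beta_peak = 0.8, beta_ic = 0, sigma_u = 0, seed = 3)
  cohort <- simulate_cohort(default_spec, cfg, phases = "fc_accent")
  ch <- cohort$choices
  p_peak <- mean(ch$choice[ch$contour == "peak"])
  p_other <- mean(ch$choice[ch$contour != "peak"])
  n_peak <- sum(ch$contour == "peak"); n_other <- sum(ch$contour != "peak")
  expect_lt(abs(p_peak - plogis(0.8)),
            3 * sqrt(plogis(0.8) * (1 - plogis(0.8)) / n_peak))
  expect_lt(abs(p_other - 0.5), 3 * sqrt(0.25 / n_other))
  # IC is null by construction
  p_hi <- mean(ch$choice[ch$ic_condition == "high"])
  p_lo <- mean(ch$choice[ch$ic_condition == "low"])
  expect_lt(abs(p_hi - p_lo), 3 * sqrt(0.25 * 4 / nrow(ch)))
})

test_that("grammar learning is detectable in a simulated cohort", {
  cfg <- sim_config(n_participants = 40, delta = 1.5, seed = 4)
  cohort <- simulate_cohort(default_spec, cfg, phases = "learning")
  res <- paired_t(cohort$ratings)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$mean_diff, 0)
})

test_that("cohorts are deterministic given the config seed", {
  cfg <- sim_config(n_participants = 4, seed = 5)
  a <- simulate_cohort(default_spec, cfg)
  b <- simulate_cohort(default_spec, cfg)
  expect_identical(a$choices, b$choices)
  expect_identical(a$ratings, b$ratings)
  # learning + two 16-item forced-choice tests per participant
  expect_identical(nrow(a$choices), 4L * 32L)
  expect_identical(nrow(a$ratings), 4L * 16L)
})

test_that("an empty cohort warns and returns empty tables", {
  cfg <- sim_config(n_participants = 0, seed = 6)
  expect_warning(out <- simulate_cohort(default_spec, cfg), "empty cohort")
  expect_identical(nrow(out$choices), 0L)
  expect_identical(nrow(out$ratings), 0L)
})
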