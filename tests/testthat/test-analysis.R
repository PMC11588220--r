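# A small hand-tabulated accent-test fixture: 4 participants x 8 items.
# Percentages below were computed by hand (spreadsheet-style) from the rows.
hand_choices <- local({
  grid <- tidyr::expand_grid(
    participant_id = sprintf("p%03d", 1:4),
    item = 1:8
  )
  grid$phase <- "fc_accent"
  grid$ic_condition <- rep(rep(c("high", "low"), each = 4), 4)
  grid$contour <- rep(c("peak", "valley", "ascending", "descending"), 8)
  grid$musician <- grid$participant_id %in% c("p001", "p002")
  grid$choice <- c(
    1, 0, 0, 0, 1, 1, 0, 1,   # p001: high 1/4, low 3/4; peak 2/2, nonpeak 1/6
    1, 1, 1, 1, 1, 1, 1, 1,   # p002: everything accented
    0, 0, 0, 0, 0, 0, 0, 0,   # p003: nothing accented
    1, 1, 0, 0, 0, 0, 0, 1    # p004: high 2/4, low 1/4; peak 1/2, nonpeak 2/6
  )
  grid
})

test_that("preference differences match the hand-tabulated oracle", {
  pref <- preference_differences(hand_choices)
  p1 <- pref[pref$participant_id == "p001", ]
  expect_equal(p1$pct_accented_high, 25)
  expect_equal(p1$pct_accented_low, 75)
  expect_equal(p1$delta_ic, -50)
  expect_equal(p1$pct_accented_peak, 100)
  expect_equal(p1$delta_peak, 100 - 100 * 2 / 6)
  # uniform responders have zero differences in both comparisons
  p2 <- pref[pref$participant_id == "p002", ]
  p3 <- pref[pref$participant_id == "p003", ]
  expect_equal(c(p2$delta_ic, p2$delta_peak, p3$delta_ic, p3$delta_peak),
               c(0, 0, 0, 0))
  p4 <- pref[pref$participant_id == "p004", ]
  expect_equal(p4$delta_ic, 25)
  expect_equal(p4$delta_peak, 50 - 100 / 3)
  expect_false(any(pref$incomplete))
})

test_that("empty strata are flagged NA, not zero-filled", {
  lopsided <- dplyr::filter(hand_choices,
                            !(participant_id == "p001" &
                                ic_condition == "high"))
  pref <- preference_differences(lopsided)
  p1 <- pref[pref$participant_id == "p001", ]
  expect_true(is.na(p1$pct_accented_high))
  expect_true(is.na(p1$delta_ic))
  expect_true(p1$incomplete)
  # and the t-test excludes them with a message
  expect_message(res <- one_sample_t(pref$delta_ic), "excluding 1")
  expect_identical(res$n, 3L)
})

test_that("t statistics match the closed form", {
  res <- one_sample_t(c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, oracle_t(c(1, 2, 3, 4, 5)), tolerance = 1e-10)
  expect_equal(res$statistic, 4.242640687, tolerance = 1e-8)
  expect_identical(res$df, 4)
  set.seed(1)
  for (i in 1:10) {
    x <- round(rnorm(sample(3:10, 1)), 3)
    if (sd(x) == 0) next
    expect_equal(one_sample_t(x)$statistic, oracle_t(x), tolerance = 1e-10)
  }
})

test_that("degenerate t inputs error explicitly", {
  expect_error(one_sample_t(c(1, 1, 1, 1)), "zero variance")
  expect_error(one_sample_t(c(2)), "at least 2")
  sym <- one_sample_t(c(2, -2, 2, -2))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
})

test_that("paired_t recovers a known rating gap", {
  ratings <- tidyr::expand_grid(
    participant_id = sprintf("p%03d", 1:6), item = 1:4,
    variant = c("grammatical", "agrammatical")
  )
  set.seed(2)
  ratings$rating <- 4 + 1.5 * (ratings$variant == "grammatical") +
    round(rnorm(nrow(ratings), 0, 0.25), 1)
  res <- paired_t(ratings)
  expect_equal(res$mean_diff, 1.5, tolerance = 0.15)
  expect_lt(res$p_value, 0.001)
  expect_identical(res$df, 5)
})

test_that("with no participant heterogeneity the GLMM matches plain logistic regression", {
  cfg <- sim_config(n_participants = 40, beta_peak = 0.8, sigma_u = 0,
                    seed = 31)
  cohort <- simulate_cohort(default_spec, cfg, phases = "fc_accent")
  # the true random-intercept variance is 0, so a boundary (singular) fit is
  # the expected outcome and is surfaced as a warning
  fit <- NULL
  expect_warning(fit <- fit_accent_glmm(cohort$choices), "singular")
  expect_lt(fit$ranef_var, 0.05)
  glm_fit <- stats::glm(
    choice ~ ic + contour + musician + ic:musician,
    data = icmelody:::prepare_accent_data(cohort$choices),
    family = stats::binomial()
  )
  expect_lt(max(abs(fit$coefficients$estimate -
                      coef(glm_fit)[fit$coefficients$term])), 0.05)
})

test_that("the accent GLMM recovers generating coefficients", {
  cfg <- sim_config(beta_peak = 0.8, beta_ic = 0, seed = 32)
  cohort <- simulate_cohort(default_spec, cfg, phases = "fc_accent")
  fit <- fit_accent_glmm(cohort$choices)
  co <- tidy(fit)
  peak <- co[co$term == "contourpeak", ]
  ic <- co[co$term == "ichigh", ]
  expect_gt(peak$conf_low, 0)                       # effect detected
  expect_lt(abs(peak$estimate - 0.8), 0.5)
  expect_true(ic$conf_low < 0 && ic$conf_high > 0)  # null covered
  expect_true(fit$converged)
  expect_equal(fit$bic, -2 * fit$loglik + fit$df * log(fit$n_obs),
               tolerance = 1e-8)
})

test_that("the IC GLMM covers a null and detects a real accent effect", {
  cfg0 <- sim_config(gamma_accent = 0, seed = 33)
  cohort0 <- simulate_cohort(default_spec, cfg0, phases = "fc_ic")
  co0 <- tidy(fit_ic_glmm(cohort0$choices))
  acc0 <- co0[co0$term == "accentedaccented", ]
  expect_true(acc0$conf_low < 0 && acc0$conf_high > 0)

  cfg1 <- sim_config(gamma_accent = 1.0, seed = 34)
  cohort1 <- simulate_cohort(default_spec, cfg1, phases = "fc_ic")
  co1 <- tidy(fit_ic_glmm(cohort1$choices))
  acc1 <- co1[co1$term == "accentedaccented", ]
  expect_gt(acc1$conf_low, 0)

  expect_error(fit_ic_glmm(cohort1$choices[0, ]), "no fc_ic records")
})

test_that("model comparison follows the likelihood-ratio arithmetic", {
  cfg <- sim_config(beta_peak = 0.8, n_participants = 30, seed = 35)
  cohort <- simulate_cohort(default_spec, cfg, phases = "fc_accent")
  full <- fit_accent_glmm(cohort$choices)

  same <- compare_models(full, full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)

  no_contour <- fit_accent_glmm(cohort$choices, drop = "contour")
  cmp <- compare_models(full, no_contour)
  expect_identical(cmp$df, 3L)   # dropping a 4-level factor frees 3 params
  expect_equal(cmp$chisq, 2 * (full$loglik - no_contour$loglik),
               tolerance = 1e-8)
  expect_equal(cmp$delta_bic, no_contour$bic - full$bic, tolerance = 1e-8)

  # dropping a main effect also removes its interaction: not nested the
  # other way around
  expect_error(compare_models(no_contour, full), "not nested")
})

test_that("the synthetic scenario reproduces the qualitative result pattern", {
  cfg <- sim_config(beta_peak = 0.8, beta_ic = 0, seed = 36)
  cohort <- simulate_cohort(default_spec, cfg, phases = "fc_accent")
  pref <- preference_differences(cohort$choices)
  expect_lt(one_sample_t(pref$delta_peak)$p_value, 0.05)
  expect_gt(one_sample_t(pref$delta_ic)$p_value, 0.05)
  full <- fit_accent_glmm(cohort$choices)
  expect_lt(compare_models(full,
                           fit_accent_glmm(cohort$choices,
                                           drop = "contour"))$p_value, 0.05)
  expect_gt(compare_models(full,
                           fit_accent_glmm(cohort$choices,
                                           drop = "ic"))$p_value, 0.05)
})
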