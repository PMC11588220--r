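#' Per-participant preference differences in the accent test
#'
#' For each participant, computes the percentage of accent-preference items
#' on which the accented member was chosen, stratified by target IC
#' condition (high vs low) and by contour (peak vs all non-peak contours
#' pooled), and the two differences in percentage points:
#' `delta_ic = pct(high) - pct(low)` and
#' `delta_peak = pct(peak) - pct(non-peak)`. Participants with an empty
#' stratum get `NA` for the affected quantities and are flagged, never
#' zero-filled; downstream t-tests drop them listwise with a logged count.
#'
#' @param choices A choice table (e.g. from [simulate_cohort()]) containing
#'   `phase == "fc_accent"` rows with columns `participant_id`,
#'   `ic_condition`, `contour`, `choice` (1 = accented chosen).
#' @return A tibble with one row per participant: the four stratified
#'   percentages, `delta_ic`, `delta_peak`, and `incomplete` (any empty
#'   stratum).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(default_grammar(), sim_config(n_participants = 8, seed = 2))
#' preference_differences(cohort$choices)
#' }
#' @export
preference_differences <- function(choices) {
  acc <- dplyr::filter(choices, .data$phase == "fc_accent")
  if (nrow(acc) == 0) abort("no fc_accent records in the choice table")
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  out <- acc |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      pct_accented_high = pct(.data$choice[.data$ic_condition == "high"]),
      pct_accented_low = pct(.data$choice[.data$ic_condition == "low"]),
      pct_accented_peak = pct(.data$choice[.data$contour == "peak"]),
      pct_accented_nonpeak = pct(.data$choice[.data$contour != "peak"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      delta_ic = .data$pct_accented_high - .data$pct_accented_low,
      delta_peak = .data$pct_accented_peak - .data$pct_accented_nonpeak,
      incomplete = is.na(.data$delta_ic) | is.na(.data$delta_peak)
    )
  out
}

new_t_result <- function(ht, n, method) {
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_diff = unname(ht$estimate[1]),
         conf_low = ht$conf.int[1], conf_high = ht$conf.int[2],
         n = n, method = method),
    class = "ic_t_test"
  )
}

#' @export
print.ic_t_test <- function(x, ...) {
  cat(sprintf("%s: t(%d) = %.4f, p = %.4g, mean difference = %.3f (n = %d)\n",
              x$method, x$df, x$statistic, x$p_value, x$mean_diff, x$n))
  invisible(x)
}

#' @rdname one_sample_t
#' @param x An `ic_t_test`.
#' @param ... Unused.
#' @method tidy ic_t_test
#' @export
tidy.ic_t_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 mean_diff = x$mean_diff, conf_low = x$conf_low,
                 conf_high = x$conf_high, n = x$n, method = x$method)
}

#' One-sample and paired t-tests for preference and learning effects
#'
#' `one_sample_t()` tests a vector of per-participant differences (e.g.
#' `delta_peak` from [preference_differences()]) against zero.
#' `paired_t()` tests grammar learning: it averages each participant's
#' similarity ratings by variant and runs a paired t-test of grammatical
#' versus agrammatical means. Both return two-sided p-values from the t
#' distribution with `n - 1` degrees of freedom. `NA` differences
#' (participants with an empty stratum) are dropped with a message giving
#' the excluded count. Zero-variance input is a degenerate test and raises
#' an explicit error.
#'
#' @param deltas Numeric vector of per-participant differences.
#' @param mu Null value. Default 0.
#' @return An `ic_t_test` object (see [tidy.ic_t_test()]).
#' @examples
#' tidy(one_sample_t(c(1, 2, 3, 4, 5)))  # t = 4.2426
#' @export
one_sample_t <- function(deltas, mu = 0) {
  n_na <- sum(is.na(deltas))
  if (n_na > 0)
    message(sprintf("one_sample_t: excluding %d participant(s) with undefined differences", n_na))
  x <- deltas[!is.na(deltas)]
  if (length(x) < 2) abort("one_sample_t requires at least 2 observations")
  if (stats::sd(x) == 0)
    abort("degenerate test: differences have zero variance")
  new_t_result(stats::t.test(x, mu = mu), length(x), "one-sample t-test")
}

#' @rdname one_sample_t
#' @param ratings A rating table with columns `participant_id`, `variant`
#'   (`"grammatical"` / `"agrammatical"`), `rating`.
#' @export
paired_t <- function(ratings) {
  by_p <- ratings |>
    dplyr::group_by(.data$participant_id, .data$variant) |>
    dplyr::summarise(mean_rating = mean(.data$rating), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "variant", values_from = "mean_rating")
  if (!all(c("grammatical", "agrammatical") %in% names(by_p)))
    abort("paired_t requires both grammatical and agrammatical ratings")
  complete <- !is.na(by_p$grammatical) & !is.na(by_p$agrammatical)
  if (sum(!complete) > 0)
    message(sprintf("paired_t: excluding %d participant(s) missing a variant", sum(!complete)))
  d <- by_p$grammatical[complete] - by_p$agrammatical[complete]
  if (length(d) < 2) abort("paired_t requires at least 2 participants")
  if (stats::sd(d) == 0)
    abort("degenerate test: differences have zero variance")
  new_t_result(stats::t.test(d, mu = 0), length(d), "paired t-test")
}

# --- binomial mixed models ---------------------------------------------------

contour_levels <- c("descending", "ascending", "peak", "valley")

prepare_accent_data <- function(choices) {
  d <- dplyr::filter(choices, .data$phase == "fc_accent")
  if (nrow(d) == 0) abort("no fc_accent records in the choice table")
  if (dplyr::n_distinct(d$participant_id) < 2)
    abort("mixed model requires at least 2 participants")
  if (dplyr::n_distinct(d$ic_condition) < 2 ||
      dplyr::n_distinct(d$contour) < 2)
    abort("mixed model requires both IC levels and at least 2 contour classes")
  dplyr::mutate(
    d,
    ic = factor(.data$ic_condition, levels = c("low", "high")),
    contour = factor(.data$contour,
                     levels = intersect(contour_levels, unique(.data$contour))),
    musician = factor(ifelse(.data$musician, "musician", "nonmusician"),
                      levels = c("nonmusician", "musician")),
    participant_id = factor(.data$participant_id)
  )
}

prepare_ic_data <- function(choices) {
  d <- dplyr::filter(choices, .data$phase == "fc_ic")
  if (nrow(d) == 0) abort("no fc_ic records in the choice table")
  if (dplyr::n_distinct(d$participant_id) < 2)
    abort("mixed model requires at least 2 participants")
  dplyr::mutate(
    d,
    accented = factor(.data$accent_arm, levels = c("plain", "accented")),
    musician = factor(ifelse(.data$musician, "musician", "nonmusician"),
                      levels = c("nonmusician", "musician")),
    participant_id = factor(.data$participant_id)
  )
}

fit_glmm <- function(data, fixed_terms, drop, task) {
  fixed_terms <- setdiff(fixed_terms, drop)
  if (any(grepl(":", fixed_terms))) {
    mains <- unique(unlist(strsplit(grep(":", fixed_terms, value = TRUE), ":")))
    missing_main <- setdiff(mains, fixed_terms)
    if (length(missing_main))
      abort(sprintf("cannot keep an interaction without its main effect(s): %s",
                    paste(missing_main, collapse = ", ")))
  }
  rhs <- paste(c(fixed_terms, "(1 | participant_id)"), collapse = " + ")
  fml <- stats::as.formula(paste("choice ~", rhs))
  fit <- lme4::glmer(fml, data = data, family = stats::binomial())

  converged <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0
  if (!converged)
    warn(paste("mixed model did not converge cleanly:",
               paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; ")))

  cc <- summary(fit)$coefficients
  z <- qnorm(0.975)
  coefs <- tibble::tibble(
    term = rownames(cc),
    estimate = cc[, "Estimate"],
    std_error = cc[, "Std. Error"],
    statistic = cc[, "z value"],
    p_value = cc[, "Pr(>|z|)"],
    conf_low = cc[, "Estimate"] - z * cc[, "Std. Error"],
    conf_high = cc[, "Estimate"] + z * cc[, "Std. Error"]
  )
  ll <- as.numeric(logLik(fit))
  structure(
    list(model = fit, task = task, fixed_terms = fixed_terms,
         formula = deparse(fml), coefficients = coefs,
         ranef_var = unname(lme4::VarCorr(fit)$participant_id[1, 1]),
         loglik = ll, df = attr(logLik(fit), "df"), bic = BIC(fit),
         n_obs = nrow(data),
         n_participants = dplyr::n_distinct(data$participant_id),
         converged = converged),
    class = "glmm_fit"
  )
}

#' Binomial mixed model for the accent-preference test
#'
#' Fits a binomial (logit) generalised mixed-effects model of whether the
#' accented member was chosen, with IC condition, melodic contour (4-level
#' categorical, reference `"descending"`), musicianship, and the IC x
#' musicianship interaction as fixed effects and a participant random
#' intercept. Estimation is delegated to [lme4::glmer()]; this function owns
#' the factor coding, design, and reporting. Confidence intervals are Wald
#' intervals on the log-odds scale. Non-convergence is reported via the
#' `converged` flag and a warning, never silently.
#'
#' @param choices A choice table with `fc_accent` rows.
#' @param drop Character vector of fixed-effect terms to omit (e.g.
#'   `"contour"`, `"ic"`, `"musician"`), for nested model comparisons with
#'   [compare_models()]. Dropping a main effect also drops interactions
#'   containing it.
#' @return A `glmm_fit` object; see [tidy.glmm_fit()] and
#'   [glance.glmm_fit()].
#' @export
fit_accent_glmm <- function(choices, drop = character()) {
  data <- prepare_accent_data(choices)
  terms <- c("ic", "contour", "musician", "ic:musician")
  if ("ic" %in% drop || "musician" %in% drop)
    drop <- union(drop, "ic:musician")
  fit_glmm(data, terms, drop, task = "fc_accent")
}

#' Binomial mixed model for the IC-preference test
#'
#' Fits a binomial (logit) mixed model of whether the high-IC member was
#' chosen, with the accent arm (both members accented vs neither),
#' musicianship, and their interaction as fixed effects and a participant
#' random intercept.
#'
#' @inheritParams fit_accent_glmm
#' @return A `glmm_fit` object.
#' @export
fit_ic_glmm <- function(choices, drop = character()) {
  data <- prepare_ic_data(choices)
  terms <- c("accented", "musician", "accented:musician")
  if ("accented" %in% drop || "musician" %in% drop)
    drop <- union(drop, "accented:musician")
  fit_glmm(data, terms, drop, task = "fc_ic")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %s: %s\n", x$task, x$formula))
  cat(sprintf("  n = %d obs, %d participants; logLik = %.3f, BIC = %.3f\n",
              x$n_obs, x$n_participants, x$loglik, x$bic))
  cat(sprintf("  random-intercept variance = %.4f; converged: %s\n",
              x$ranef_var, x$converged))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidiers for fitted mixed models
#'
#' @param x A `glmm_fit`.
#' @param ... Unused.
#' @return `tidy()`: the fixed-effect coefficient table (term, estimate,
#'   std_error, statistic, p_value, Wald 95% conf_low/conf_high).
#'   `glance()`: a one-row tibble with `loglik`, `df`, `bic`, `ranef_var`,
#'   `n_obs`, `n_participants`, `converged`.
#' @method tidy glmm_fit
#' @export
tidy.glmm_fit <- function(x, ...) x$coefficients

#' @rdname tidy.glmm_fit
#' @method glance glmm_fit
#' @export
glance.glmm_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, df = x$df, bic = x$bic,
                 ranef_var = x$ranef_var, n_obs = x$n_obs,
                 n_participants = x$n_participants, converged = x$converged)
}

#' Likelihood-ratio comparison of nested mixed models
#'
#' Compares a full and a reduced fit of the same data by the likelihood
#' ratio: `chisq = 2 (loglik_full - loglik_reduced)` on `df` equal to the
#' parameter-count difference, with the p-value from the chi-squared
#' distribution, plus the BIC difference (reduced minus full). The reduced
#' model's fixed effects must be a subset of the full model's and both fits
#' must use the same observations.
#'
#' @param full,reduced `glmm_fit` objects.
#' @return A one-row tibble: `chisq`, `df`, `p_value`, `delta_bic`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(default_grammar(),
#'                           sim_config(n_participants = 20, seed = 3))
#' full <- fit_accent_glmm(cohort$choices)
#' compare_models(full, fit_accent_glmm(cohort$choices, drop = "contour"))
#' }
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "glmm_fit"), inherits(reduced, "glmm_fit"))
  if (!all(reduced$fixed_terms %in% full$fixed_terms))
    abort("models are not nested: reduced fixed effects are not a subset of the full model's")
  if (full$n_obs != reduced$n_obs || full$task != reduced$task)
    abort("models were not fit to the same data")
  chisq <- 2 * (full$loglik - reduced$loglik)
  if (chisq < -1e-6)
    abort("full model has lower likelihood than the nested reduced model; refit failed to converge")
  chisq <- max(chisq, 0)
  df <- as.integer(full$df - reduced$df)
  tibble::tibble(
    chisq = chisq,
    df = df,
    p_value = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else 1,
    delta_bic = reduced$bic - full$bic
  )
}
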