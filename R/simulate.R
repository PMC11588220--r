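#' Simulation configuration for a synthetic cohort
#'
#' Defines the generative model for synthetic participant behaviour. Forced
#' choices are Bernoulli draws whose log-odds are linear in the trial
#' covariates plus a participant random intercept `u ~ N(0, sigma_u^2)`:
#'
#' * accent-preference test, probability of choosing the accented member:
#'   `plogis(beta0 + beta_peak*[contour == peak] + beta_ic*[high IC] +
#'   beta_mus*[musician] + beta_ic_mus*[high IC]*[musician] + u)`;
#' * IC-preference test, probability of choosing the high-IC member:
#'   `plogis(gamma0 + gamma_accent*[accented arm] + gamma_mus*[musician] +
#'   gamma_accent_mus*[accented]*[musician] + u)`.
#'
#' Similarity ratings in the learning test are
#' `round(clamp(rating_base + u + delta*[grammatical] + noise, 1, 7))` with
#' `noise ~ N(0, rating_noise^2)` per trial.
#'
#' The default scenario encodes the qualitative behavioural pattern the
#' package's analysis stage is designed to detect: a positive peak-contour
#' effect on accent preference, null IC, musicianship and interaction
#' effects, a null IC-preference model, participant heterogeneity
#' `sigma_u = 0.5`, and clear grammar learning (`delta = 1.5` rating points).
#'
#' @param n_participants Cohort size. Default 78.
#' @param musician_fraction Proportion of musicians. Default 0.4.
#' @param beta0,beta_peak,beta_ic,beta_mus,beta_ic_mus Accent-test log-odds
#'   coefficients. Defaults 0, 0.5, 0, 0, 0.
#' @param gamma0,gamma_accent,gamma_mus,gamma_accent_mus IC-test log-odds
#'   coefficients. Defaults all 0.
#' @param sigma_u SD of the participant random intercept. Default 0.5.
#' @param delta Mean rating gap (grammatical minus agrammatical), 1-7 scale.
#'   Default 1.5.
#' @param rating_base Baseline rating. Default 4.
#' @param rating_noise SD of per-trial rating noise. Default 1.
#' @param seed Master seed for the cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 78L, musician_fraction = 0.4,
                       beta0 = 0, beta_peak = 0.5, beta_ic = 0, beta_mus = 0,
                       beta_ic_mus = 0, gamma0 = 0, gamma_accent = 0,
                       gamma_mus = 0, gamma_accent_mus = 0, sigma_u = 0.5,
                       delta = 1.5, rating_base = 4, rating_noise = 1,
                       seed = NULL) {
  stopifnot(n_participants >= 0, musician_fraction >= 0,
            musician_fraction <= 1, sigma_u >= 0, rating_noise >= 0)
  structure(
    list(n_participants = as.integer(n_participants),
         musician_fraction = musician_fraction, beta0 = beta0,
         beta_peak = beta_peak, beta_ic = beta_ic, beta_mus = beta_mus,
         beta_ic_mus = beta_ic_mus, gamma0 = gamma0,
         gamma_accent = gamma_accent, gamma_mus = gamma_mus,
         gamma_accent_mus = gamma_accent_mus, sigma_u = sigma_u,
         delta = delta, rating_base = rating_base,
         rating_noise = rating_noise, seed = seed),
    class = "sim_config"
  )
}

#' Draw participant profiles
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return A tibble with `participant_id`, `musician`, and random intercept
#'   `u` drawn from `N(0, sigma_u^2)`.
#' @export
participant_profiles <- function(cfg, seed = cfg$seed) {
  with_seed(seed, {
    n <- cfg$n_participants
    n_mus <- round(n * cfg$musician_fraction)
    musician <- sample(rep(c(TRUE, FALSE), c(n_mus, n - n_mus)))
    tibble::tibble(
      participant_id = sprintf("p%03d", seq_len(n)),
      musician = musician,
      u = rnorm(n, 0, cfg$sigma_u)
    )
  })
}

#' Simulate one similarity rating
#'
#' @param profile One row of [participant_profiles()].
#' @param trial One learning-trial row of a schedule's `trials` tibble.
#' @param cfg A [sim_config()].
#' @return An integer rating 1-7.
#' @export
simulate_similarity_rating <- function(profile, trial, cfg) {
  if (trial$kind != "learning")
    abort("simulate_similarity_rating() requires a learning trial")
  grammatical <- trial$variant == "grammatical"
  raw <- cfg$rating_base + profile$u + cfg$delta * grammatical +
    rnorm(1, 0, cfg$rating_noise)
  as.integer(round(clamp(raw, 1, 7)))
}

# Choice probability implied by the generative model for one trial.
choice_probability <- function(cfg, kind, u, musician, ic_condition = NA,
                               contour = NA, accent_arm = NA) {
  eta <- switch(
    kind,
    fc_accent = cfg$beta0 + cfg$beta_peak * (contour == "peak") +
      cfg$beta_ic * (ic_condition == "high") + cfg$beta_mus * musician +
      cfg$beta_ic_mus * (ic_condition == "high") * musician + u,
    fc_ic = cfg$gamma0 + cfg$gamma_accent * (accent_arm == "accented") +
      cfg$gamma_mus * musician +
      cfg$gamma_accent_mus * (accent_arm == "accented") * musician + u,
    abort(sprintf("'%s' is not a forced-choice trial kind", kind))
  )
  plogis(eta)
}

#' Simulate one forced choice
#'
#' Draws a Bernoulli response for an accent-preference or IC-preference item
#' under the configured logistic model. For `fc_accent` trials, `choice = 1`
#' means the accented member was chosen; for `fc_ic` trials, the high-IC
#' member.
#'
#' @param profile One row of [participant_profiles()].
#' @param item One forced-choice trial row.
#' @param cfg A [sim_config()].
#' @return A one-row tibble: `participant_id`, `musician`, `phase`,
#'   `item_id`, `ic_condition`, `contour`, `accent_arm`,
#'   `presentation_order`, `p`, `choice`.
#' @export
simulate_forced_choice <- function(profile, item, cfg) {
  p <- choice_probability(cfg, item$kind, profile$u, profile$musician,
                          ic_condition = item$ic_condition,
                          contour = item$contour,
                          accent_arm = item$accent_arm)
  tibble::tibble(
    participant_id = profile$participant_id, musician = profile$musician,
    phase = item$kind, item_id = item$item_id,
    ic_condition = item$ic_condition, contour = item$contour,
    accent_arm = item$accent_arm,
    presentation_order = item$presentation_order,
    p = p, choice = rbinom(1, 1, p)
  )
}

#' Simulate a full synthetic cohort
#'
#' For each participant, builds a participant-specific test schedule
#' (learning test plus both forced-choice tests, from a participant-derived
#' seed) and simulates every response under the configured generative model.
#' The passive exposure phase solicits no responses and is skipped unless
#' `include_exposure = TRUE`. The result is deterministic given `cfg$seed`.
#'
#' @param spec A `grammar_spec`.
#' @param cfg A [sim_config()] with a non-`NULL` `seed` for reproducibility.
#' @param phases Which response-yielding phases to build and simulate, a
#'   subset of `c("learning", "fc_accent", "fc_ic")`. Restricting phases
#'   (e.g. to `"fc_accent"` for an accent-test power study) skips the unused
#'   schedule builds.
#' @param include_exposure Also build each participant's exposure schedule
#'   (slower; responses are not simulated for passive trials). Default
#'   `FALSE`.
#' @return A list with `choices` (long-format choice table over both
#'   forced-choice tests), `ratings` (learning-test rating table), and
#'   `profiles`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(default_grammar(), sim_config(n_participants = 6, seed = 1))
#' head(cohort$choices)
#' }
#' @export
simulate_cohort <- function(spec, cfg,
                            phases = c("learning", "fc_accent", "fc_ic"),
                            include_exposure = FALSE) {
  phases <- match.arg(phases, several.ok = TRUE)
  profiles <- participant_profiles(cfg)
  if (cfg$n_participants == 0L) {
    warn("simulating an empty cohort (n_participants = 0)")
    return(list(choices = tibble::tibble(), ratings = tibble::tibble(),
                profiles = profiles))
  }
  choices <- vector("list", cfg$n_participants)
  ratings <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    prof <- profiles[i, ]
    pseed <- if (is.null(cfg$seed)) NULL else derive_seed(cfg$seed, i + 1000L)
    res <- with_seed(pseed, {
      out <- list(r = NULL, ch = NULL)
      if (include_exposure) build_exposure_schedule(spec)
      if ("learning" %in% phases) {
        lt <- build_learning_test(spec)$trials
        grammatical <- lt$variant == "grammatical"
        raw <- cfg$rating_base + prof$u + cfg$delta * grammatical +
          rnorm(nrow(lt), 0, cfg$rating_noise)
        out$r <- tibble::tibble(
          participant_id = prof$participant_id, musician = prof$musician,
          item_id = lt$item_id, variant = lt$variant,
          rating = as.integer(round(clamp(raw, 1, 7)))
        )
      }
      fc <- list()
      if ("fc_accent" %in% phases)
        fc$fca <- build_accent_preference_test(spec)$trials
      if ("fc_ic" %in% phases)
        fc$fci <- build_ic_preference_test(spec)$trials
      if (length(fc)) {
        items <- dplyr::bind_rows(fc)
        p <- vapply(seq_len(nrow(items)), function(k)
          choice_probability(cfg, items$kind[k], prof$u, prof$musician,
                             ic_condition = items$ic_condition[k],
                             contour = items$contour[k],
                             accent_arm = items$accent_arm[k]),
          numeric(1))
        out$ch <- tibble::tibble(
          participant_id = prof$participant_id, musician = prof$musician,
          phase = items$kind, item_id = items$item_id,
          ic_condition = items$ic_condition, contour = items$contour,
          accent_arm = items$accent_arm,
          presentation_order = items$presentation_order,
          p = p, choice = rbinom(nrow(items), 1, p)
        )
      }
      out
    })
    ratings[[i]] <- res$r
    choices[[i]] <- res$ch
  }
  list(choices = dplyr::bind_rows(choices),
       ratings = dplyr::bind_rows(ratings),
       profiles = profiles)
}
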