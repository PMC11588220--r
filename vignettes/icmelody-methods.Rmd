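---
title: "Controlled-surprisal melody generation and accent-preference analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlled-surprisal melody generation and accent-preference analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmelody)
```

## The scientific problem

When listeners judge where a dynamic accent (a louder note) *should* fall in
a melody, two kinds of structural salience compete: Gestalt salience, driven
by the local melodic shape (a note at the peak of the contour), and
statistical salience, driven by how unexpected the note is given its context
— its information content (IC), or surprisal,

$$\mathrm{IC}(x \mid c) = -\log_2 p(x \mid c).$$

Disentangling the two requires stimuli in which contour and surprisal vary
independently, something natural music does not provide. `icmelody`
implements a complete experiment-engineering and analysis pipeline around an
artificial first-order Markov melodic grammar in which both properties are
under exact control: stimulus generation, calibration verification, protocol
assembly, MIDI rendering, synthetic-cohort simulation, and the preference
statistics (t-tests on per-participant preference differences and binomial
mixed-effects models with nested model comparison).

## The grammar

Melodies are sequences of scale degrees 1–7 (degree 7 is degree 1 an octave
up) assembled from five cells, each a small first-order Markov chain:

* a **start** cell (1–3 notes), an **intermediate** cell (2–4 notes) and an
  **end** cell (2–3 notes) supply filler material;
* two **IC cells** of exactly two notes each — a fixed *context* degree
  followed by one of two *target* degrees one scale degree away. In the
  IC-α cell the context is degree 3: the ascending target 4 occurs with
  probability 0.95 (low IC) and the descending target 2 with probability
  0.05 (high IC). In the IC-β cell the context is degree 5 and the roles
  are mirrored: descending 4 is the 0.95 branch, ascending 6 the 0.05
  branch. Crossing the two cells de-confounds contour direction from
  surprisal.

Exposure melodies concatenate start → IC → intermediate → IC → end, with
the order of the two IC cells flipped at random; total lengths are 9–14
notes. Forced-choice melodies drop the intermediate cell and one IC cell
(start 2–3 notes, end 3–4 notes), giving 7–9 notes with the single target
always in the middle third of the melody.

Three global constraints hold everywhere, including across cell boundaries:
no repeated notes, no step larger than 4 scale degrees, and the four
context–target pairs (5→4, 5→6, 3→4, 3→2) never occur outside the IC
cells. The last constraint is what makes the *corpus-level* conditional
probability of each target interpretable: every occurrence of, say, 5→4 is
an IC-cell event.

```{r grammar}
spec <- default_grammar()
spec
validate_grammar(spec)   # zero rows: all invariants hold
```

## Calibration of the filler cells

The filler-cell transition tables are package defaults (the cell diagrams
of the original design are not recoverable as numbers), chosen once to
satisfy two quantitative goals and then frozen:

1. **Corpus surprisal.** Pooled over a large corpus, the IC of a designed
   transition is $-\log_2\!\big(p_\text{branch} \times s\big)$, where $s$
   is the share of the context degree's occurrences that fall inside its IC
   cell. The tables route melodies through degrees 3 and 5 about once per
   melody outside the IC cells, so $s \approx 0.5$ and the 0.95 branches
   land near $-\log_2(0.95 \times 0.5) \approx 1.07$ bits while the 0.05
   branches land near $-\log_2(0.05 \times 0.5) \approx 5.3$ bits.
2. **Target-note frequency.** The three target degrees (2, 4, 6) should
   occur at similar overall rates (within 5 percentage points), so that
   surprisal is not confounded with plain familiarity. Because degree 4 is
   the 0.95 branch of *both* IC cells, the filler tables deliberately route
   very little additional mass into degree 4 and more into degrees 2 and 6.

`corpus_report()` verifies both properties, plus length bounds, on any
generated corpus; the calibration bands (low-IC within [0.7, 1.4] bits,
high-IC within [5, 6] bits, spread ≤ 5 pp) operationalise the design goals
and are override-able arguments, not hidden constants.

```{r calibration}
corpus <- generate_corpus(spec, 1000, seed = 1)
glance(corpus_report(corpus))
```

At the package's reference scale of 5,000 melodies (the default in
`scripts/acceptance.R`) the same flags pass with low-IC ≈ 1.0–1.1 bits,
high-IC ≈ 5.2–5.3 bits and a spread near 4 pp; 1,000 melodies are used
here to keep the vignette fast.

## Pitch mapping and rendering

Degrees map to pitches through an asymmetric hexascale — six intervals
summing to an octave, default `1 2 2 1 3 3` semitones, validated to be
rotationally asymmetric — and a sliding window on the repeating lattice.
The six window positions are the six tonic listening conditions; each gives
a distinct inter-degree interval pattern, which is what a listener can
learn. Degree 7 is always degree 1 plus 12 semitones.

```{r pitch}
tidy(build_pitch_mapping(hexascale(), 0))
```

Rendering writes standard MIDI files: isochronous piano tones (500 ms
inter-onset interval, 450 ms duration, velocity 80), with accented targets
at velocity 80 + 32. The accent magnitude is a rendering parameter with no
published reference value; +32 is clearly audible without clipping the
0–127 velocity range. Agrammatical stimuli for the learning test swap the
*rendered pitches* of degrees 5 and 6 while leaving the degree sequence
untouched, so the swap is an involution applied at the mapping stage.

## Protocol

`build_experiment()` assembles the full per-participant schedule:

* **Exposure**: 45 passive trials × 4 melodies = 180 exposure melodies,
  with 22 active trials (attention : liking = 2 : 1) interleaved at random
  positions, never first and never adjacent — an average of one active
  trial per two passive trials. Attention trials pair a long and a short
  melody (easy 7 vs 14, intermediate 7 vs 9, hard 12 vs 14 notes); long
  melodies come from the exposure grammar conditioned on length by
  rejection, short ones from the forced-choice grammar.
* **Learning test**: 16 melodies, 8 grammatical + 8 agrammatical, random
  order, each rated 1–7 for similarity to the exposure set.
* **Accent-preference test**: 16 items of identical melody pairs, accented
  vs plain target, half high-IC and half low-IC, with each contour class
  (peak, valley, ascending, descending) appearing four times. The builder
  realises a requested contour by choosing the unique compatible IC cell
  and conditioning the first end-cell note on the contour class — a
  distributional no-op relative to rejection sampling, since the contour
  depends only on that note.
* **IC-preference test**: 16 items of matched pairs differing only at the
  target (the other branch of the same IC cell, identical flanking notes);
  half with both members accented, half with neither.

Where the protocol leaves counts unstated we fixed defaults once: the 2:1
attention-to-liking split, the no-adjacent-active placement rule, and the
exact 4-per-contour balance (the source design states only that all four
contours were present). All of these are arguments to the builders.

## The response simulator

`simulate_cohort()` is a synthetic stand-in for human participants with the
statistical structure the analysis assumes — not a cognitive model. Each
participant carries a random intercept $u \sim N(0, \sigma_u^2)$; forced
choices are Bernoulli draws with logistic link over the item covariates
(contour, IC condition, musicianship and the IC × musicianship interaction
for the accent test; accent arm, musicianship and their interaction for the
IC test); similarity ratings are a clamped, rounded linear model with a
grammaticality offset δ. The default scenario encodes the qualitative
pattern the pipeline is designed to detect — β_peak = 0.5 with every other
choice coefficient zero, σ_u = 0.5, δ = 1.5 rating points, 40% musicians —
so that, by construction, contour has a real effect and IC none. What
passing tests against this generator shows is that the *analysis recovers
whatever structure the generator put in*; it says nothing about human
behaviour, which is why the original study's human statistics are
explicitly out of the package's scope and are approached only as
parameter-recovery checks.

```{r cohort}
cohort <- simulate_cohort(spec, sim_config(n_participants = 20,
                                           beta_peak = 0.8, seed = 42),
                          phases = "fc_accent")
head(cohort$choices, 3)
```

Features of real data the generator does not emulate: response times,
attention lapses, learning dynamics across the session, and item-level
random effects. A liking-drift hook exists in the protocol builder's data
only as trial metadata; it feeds no analysis.

## Analysis

The analysis stage mirrors the standard two-step treatment of
two-alternative forced-choice preference data:

* `preference_differences()` computes, per participant, the percentage of
  accent-test items on which the accented member was chosen, stratified by
  IC condition and by peak vs non-peak contour (the binary collapse pools
  valley, ascending and descending), and the two differences in percentage
  points. Participants with an empty stratum are flagged `NA` and excluded
  listwise from the corresponding t-test, with a logged count.
* `one_sample_t()` / `paired_t()` wrap the classical t-tests with explicit
  degenerate-input errors (zero variance, n < 2).
* `fit_accent_glmm()` / `fit_ic_glmm()` fit binomial (logit) mixed models
  with a participant random intercept via `lme4::glmer()`; the package owns
  the factor coding (treatment coding; contour reference level
  `"descending"`, chosen because no reference level is published), the
  design, Wald 95% intervals, BIC, and a convergence flag that is never
  silently ignored.
* `compare_models()` performs the likelihood-ratio test between nested
  fits (χ² = 2Δloglik, df = parameter difference) and reports ΔBIC,
  reproducing the full-vs-reduced comparison table structure.

No multiple-testing correction is applied, matching the source analysis.

```{r analysis}
pref <- preference_differences(cohort$choices)
tidy(one_sample_t(pref$delta_peak))
full <- fit_accent_glmm(cohort$choices)
tidy(full)
compare_models(full, fit_accent_glmm(cohort$choices, drop = "contour"))
```

## Numerical choices and degenerate inputs

* **Constrained sampling** is exact with respect to the declared
  conditional tables: illegal continuations are excluded by construction
  within cells, and cross-boundary conflicts are handled by
  reject-and-resample with a cap of 100 whole-melody attempts, after which
  a classed error (`icmelody_dead_end`) names the stranded degree.
* **RNG**: corpus and cohort generators derive one substream per melody or
  participant from the master seed (recorded as `seed_tag`), so individual
  stimuli replay bit-exactly without regenerating the whole corpus.
* **Unobserved transitions** have infinite IC; `information_content()`
  returns `Inf` as an explicit sentinel, never `NaN`, and `corpus_report()`
  converts missing reserved pairs at n ≥ 1000 into a calibration failure.
* **Ties and orderings** (module order, IC cell in test melodies,
  presentation order within a pair) are uniform 50/50 draws recorded in the
  schedule.
* **Boundary variance fits**: with σ_u = 0 the mixed model sits on the
  boundary; the fit is returned with `converged = FALSE` and a warning, and
  its fixed effects agree with pooled logistic regression (tested).

## Problem sizes

The shipped checks use 5,000-melody corpora for calibration, 10,000 samples
per IC cell for branch-rate verification, 10,000 melodies for the
constraint suite, and 60 replicate cohorts of 78 participants for the
mixed-model recovery study. These sizes make the Monte-Carlo error small
relative to every tolerance band used (e.g. the binomial SE of the branch
rate at n = 10,000 is 0.2 percentage points) while keeping a full run in
the minutes range on a single core.

## Known limitations

* The filler tables are calibrated stand-ins, not the original cell
  diagrams; any table set satisfying the constraint and calibration
  invariants is admissible, and the defaults are one such set.
* Only first-order grammars are supported; no higher-order or
  variable-order models, and no rhythm or meter variation (all stimuli are
  isochronous by design).
* MIDI output is deliberately minimal (format 0, one track, one program);
  no audio synthesis or loudness normalisation.
* The simulator's effect sizes are scenario parameters, not estimates of
  human effect sizes, which are not recoverable from published summary
  statistics.
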