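# icmelody

Artificial-grammar melodies with controlled information content, and the
statistics of accent preference.

## The problem

Listeners tend to prefer dynamic accents (a note played louder than its
neighbours) on structurally salient notes. Salience can come from two very
different sources: the **Gestalt shape** of the melody — a note at the peak
of the local contour — or the note's **statistical unexpectedness** given
its context, its information content (surprisal)

```
IC(x | c) = -log2 p(x | c).
```

In natural music the two are confounded. `icmelody` builds the kind of
stimulus system and analysis pipeline needed to separate them: melodies
generated from an artificial first-order Markov grammar in which designated
target notes have exactly controlled conditional probability (a 0.95 branch
≈ 1 bit of surprisal at corpus level, a 0.05 branch ≈ 5–6 bits) and
independently varied contour (peak, valley, ascending, descending). The
package is for researchers in auditory cognition and music psychophysics
who need IC-calibrated melodic stimuli, a reproducible two-alternative
forced-choice protocol, or a reference implementation of the accompanying
analysis.

It provides, end to end:

* **Grammar and sampling** — a validated five-cell Markov grammar
  (`default_grammar()`, `validate_grammar()`) generating 9–14-note exposure
  melodies with two IC targets and 7–9-note forced-choice melodies with one
  mid-melody target (`generate_exposure_melody()`, `generate_test_melody()`,
  `generate_corpus()`), under global no-repeat / max-step-4 /
  reserved-pair constraints.
* **Pitch and rendering** — asymmetric-hexascale pitch mapping with a
  sliding window giving six tonic conditions (`hexascale()`,
  `build_pitch_mapping()`) and standard MIDI output with velocity accents
  (`render_midi()`, `write_melody_midi()`, `read_midi_notes()`).
* **Calibration statistics** — pooled transition counts, surprisal, and a
  calibration report with explicit pass/fail flags
  (`empirical_transitions()`, `information_content()`, `corpus_report()`).
* **Protocol assembly** — the full experiment schedule: 180 exposure
  melodies in 45 passive trials with interleaved attention/liking trials, a
  16-item grammar-learning test (8 grammatical + 8 agrammatical with the
  degree 5/6 pitch swap), and two 16-item forced-choice tests
  (`build_experiment()` and the per-phase builders), serializable to
  JSON-lines manifests.
* **Synthetic cohorts** — a response simulator with participant random
  intercepts and configurable effect sizes (`sim_config()`,
  `simulate_cohort()`).
* **Analysis** — per-participant preference differences with t-tests
  (`preference_differences()`, `one_sample_t()`, `paired_t()`), binomial
  mixed-effects models with participant random intercepts
  (`fit_accent_glmm()`, `fit_ic_glmm()`), and nested likelihood-ratio /
  BIC model comparison (`compare_models()`), with `tidy()` / `glance()` /
  `autoplot()` methods throughout.

## Worked example

```r
library(icmelody)

spec <- default_grammar()

# 1. generate a seeded exposure corpus and verify its calibration
corpus <- generate_corpus(spec, 5000, seed = 1)
corpus_report(corpus)
#> <corpus_summary> 5000 melodies, lengths 9-14
#> IC of reserved context-target pairs (bits):
#>  context target  branch   ic_bits
#>        5      4  low_ic 1.1024326
#>        3      4  low_ic 0.9880831
#>        5      6 high_ic 5.3083922
#>        3      2 high_ic 5.1822505
#> target-degree frequency spread: 4.24 percentage points
#> calibration: PASS
```

The 0.95 branches sit near 1 bit of corpus-level surprisal and the 0.05
branches above 5 bits, while the three target degrees occur at overall
rates within 4.24 percentage points of one another — surprisal is
controlled without confounding it with note frequency, and every melody is
9–14 notes long.

```r
# 2. simulate a 78-participant cohort under the default scenario:
#    a real peak-contour effect (log-odds 0.5), no IC effect
cohort <- simulate_cohort(spec, sim_config(beta_peak = 0.5, seed = 1))

# grammar learning: grammatical melodies rated ~1.5 points higher
paired_t(cohort$ratings)
#> paired t-test: t(77) = 26.1849, p = 4.366e-40, mean difference = 1.457 (n = 78)

# 3. per-participant preference differences
pref <- preference_differences(cohort$choices)
one_sample_t(pref$delta_peak)
#> one-sample t-test: t(77) = 2.4937, p = 0.01478, mean difference = 8.547 (n = 78)
one_sample_t(pref$delta_ic)
#> one-sample t-test: t(77) = 0.7759, p = 0.4402, mean difference = 1.923 (n = 78)

# 4. binomial mixed model and nested comparisons
full <- fit_accent_glmm(cohort$choices)
compare_models(full, fit_accent_glmm(cohort$choices, drop = "contour"))
#>   chisq    df p_value delta_bic
#> 1  9.49     3  0.0235     -11.9
compare_models(full, fit_accent_glmm(cohort$choices, drop = "ic"))
#>   chisq    df p_value delta_bic
#> 1 0.486     2   0.784     -13.8
```

The analysis recovers exactly the structure the generator put in:
participants prefer the accented version more often when the target is a
contour peak (Δ = +8.5 percentage points, p ≈ 0.015; dropping contour
significantly worsens the mixed model, p ≈ 0.024), while the high- vs
low-IC difference is null (p ≈ 0.44; dropping IC changes nothing,
p ≈ 0.78).

To export one participant's complete experiment (schedule manifest plus
rendered MIDI stimuli):

```sh
Rscript scripts/build_experiment.R --seed 1 --tonic-condition 0 --out experiment_out
```

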