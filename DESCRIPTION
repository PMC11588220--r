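Package: icmelody
Title: Artificial-Grammar Melodies with Controlled Information Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing an auditory statistical-learning
    experiment based on an artificial first-order Markov melodic grammar.
    Generates exposure and forced-choice melodies whose designated target notes
    carry controlled information content (surprisal) and melodic contour, maps
    scale degrees to pitches through an asymmetric hexascale with a sliding
    window, writes standard MIDI files, verifies corpus-level calibration of
    transition surprisal and note frequencies, assembles the full experiment
    protocol (exposure, grammar-learning test, two-alternative forced-choice
    tests), simulates participant responses under configurable effect sizes,
    and runs the preference statistics: per-participant preference differences
    with t-tests, paired grammar-learning tests, binomial mixed-effects models
    with participant random intercepts, and nested model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
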