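# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Three-point comparison oracle for contour classification.
oracle_contour <- function(prev, target, nxt) {
  if (prev < target) {
    if (nxt < target) "peak" else "ascending"
  } else {
    if (nxt > target) "valley" else "descending"
  }
}

# Brute-force ordered-pair tally over a list of degree vectors.
oracle_transition_counts <- function(degree_list) {
  counts <- matrix(0L, 7, 7, dimnames = list(1:7, 1:7))
  for (d in degree_list) {
    for (k in seq_len(length(d) - 1L)) {
      counts[d[k], d[k + 1L]] <- counts[d[k], d[k + 1L]] + 1L
    }
  }
  counts
}

# Textbook one-sample t statistic.
oracle_t <- function(x, mu = 0) {
  (mean(x) - mu) / (sd(x) / sqrt(length(x)))
}

# All ordered degree triples that the grammar could ever present around a
# note: adjacent degrees differ and steps are at most 4.
legal_triples <- function() {
  g <- expand.grid(prev = 1:7, target = 1:7, nxt = 1:7)
  g[g$prev != g$target & g$nxt != g$target &
      abs(g$prev - g$target) <= 4 & abs(g$nxt - g$target) <= 4, ]
}

default_spec <- default_grammar()
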