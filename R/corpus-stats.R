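#' Empirical first-order transition matrix of a corpus
#'
#' Tallies ordered adjacent degree pairs position by position within each
#' melody, pooled over melodies; pairs never cross melody boundaries. Rows
#' index the context degree, columns the next degree.
#'
#' @param corpus A corpus tibble from [generate_corpus()], or a list of
#'   integer degree vectors.
#' @return A `transition_matrix` object with elements `counts` (7x7 integer)
#'   and `probabilities` (row-normalised; rows with no observations are
#'   `NA`, flagged undefined).
#' @examples
#' tm <- empirical_transitions(list(c(1, 2, 3, 4), c(1, 2, 1, 2)))
#' tm$probabilities["1", "2"]  # 1.0
#' @export
empirical_transitions <- function(corpus) {
  degs <- if (is.data.frame(corpus)) corpus$degrees else corpus
  if (length(degs) == 0) abort("empty corpus")
  counts <- matrix(0L, 7, 7, dimnames = list(DEGREES, DEGREES))
  for (d in degs) {
    if (length(d) < 2L) next
    from <- d[-length(d)]
    to <- d[-1]
    for (k in seq_along(from))
      counts[from[k], to[k]] <- counts[from[k], to[k]] + 1L
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, NA_real_, rs)
  structure(list(counts = counts, probabilities = probs),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix>", sum(x$counts), "pooled transitions\n")
  print(round(x$probabilities, 3))
  invisible(x)
}

#' @rdname empirical_transitions
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return For `tidy()`: a long tibble with `context`, `target`, `n`,
#'   `probability`, `ic_bits`.
#' @method tidy transition_matrix
#' @export
tidy.transition_matrix <- function(x, ...) {
  grid <- tidyr::expand_grid(context = DEGREES, target = DEGREES)
  dplyr::mutate(
    grid,
    n = x$counts[cbind(.data$context, .data$target)],
    probability = x$probabilities[cbind(.data$context, .data$target)],
    ic_bits = ifelse(is.na(.data$probability) | .data$probability == 0,
                     Inf, -log2(.data$probability))
  )
}

#' Information content of a transition
#'
#' The information content (surprisal) of observing `target` after `context`
#' is `-log2 p(target | context)` under the corpus's pooled first-order
#' transition probabilities. Events that were never observed (probability
#' zero or an undefined row) return `Inf` as an explicit infinite-surprisal
#' sentinel rather than `NaN`.
#'
#' @param matrix A `transition_matrix` from [empirical_transitions()].
#' @param context,target Scale degrees 1-7. Vectorised.
#' @return Information content in bits (non-negative, possibly `Inf`).
#' @examples
#' tm <- empirical_transitions(list(c(1, 2), c(1, 3)))
#' information_content(tm, 1, 2)  # -log2(0.5) = 1 bit
#' @export
information_content <- function(matrix, context, target) {
  stopifnot(inherits(matrix, "transition_matrix"))
  p <- matrix$probabilities[cbind(context, target)]
  ifelse(is.na(p) | p == 0, Inf, -log2(p))
}

#' Calibration report for a generated corpus
#'
#' Summarises the statistics the stimulus design controls: the corpus-level
#' information content of the four reserved context-target pairs, the
#' relative frequencies of the target degrees (2, 4, 6) as a percentage of
#' all notes, and the melody length distribution. Calibration flags check
#' that low-IC pairs (5-4, 3-4) fall in `ic_low_band`, high-IC pairs (5-6,
#' 3-2) in `ic_high_band`, the target-frequency spread (maximum pairwise
#' difference) is at most `freq_spread_max` percentage points, and all
#' lengths lie within `length_bounds`.
#'
#' @param corpus A corpus tibble of exposure melodies from one grammar.
#' @param ic_low_band,ic_high_band Tolerance bands (bits) operationalising
#'   the designed "approximately 1" and "approximately 5-6" bit surprisal of
#'   the two branch types. Defaults `c(0.7, 1.4)` and `c(5, 6)`.
#' @param freq_spread_max Maximum allowed target-frequency spread in
#'   percentage points. Default 5.
#' @param length_bounds Allowed melody lengths. Default `c(9, 14)`.
#' @return A `corpus_summary` object: `n_melodies`, `length_histogram`,
#'   `target_frequencies` (percent of all notes), `freq_spread`, `ic_table`
#'   (one row per reserved pair), and `flags` (named logicals; also
#'   `all_pass`). If any reserved pair is unobserved in a corpus of at least
#'   1000 melodies, the corresponding IC is `Inf` and calibration fails.
#' @examples
#' \donttest{
#' corpus <- generate_corpus(default_grammar(), 500, seed = 1)
#' glance(corpus_report(corpus))
#' }
#' @export
corpus_report <- function(corpus, ic_low_band = c(0.7, 1.4),
                          ic_high_band = c(5, 6), freq_spread_max = 5,
                          length_bounds = c(9L, 14L)) {
  tm <- empirical_transitions(corpus)

  ic_table <- tibble::tibble(
    context = c(5L, 3L, 5L, 3L),
    target = c(4L, 4L, 6L, 2L),
    branch = c("low_ic", "low_ic", "high_ic", "high_ic"),
    ic_bits = information_content(tm, c(5L, 3L, 5L, 3L), c(4L, 4L, 6L, 2L))
  )

  all_deg <- unlist(corpus$degrees)
  freq <- 100 * tabulate(all_deg, nbins = 7L) / length(all_deg)
  target_deg <- c(2L, 4L, 6L)
  tf <- tibble::tibble(degree = target_deg, percent = freq[target_deg])
  spread <- max(dist(tf$percent))

  lengths <- corpus$length
  hist <- dplyr::count(tibble::tibble(length = lengths), .data$length)

  low <- ic_table$ic_bits[ic_table$branch == "low_ic"]
  high <- ic_table$ic_bits[ic_table$branch == "high_ic"]
  unobserved <- !is.finite(ic_table$ic_bits)
  flags <- c(
    low_ic_in_band = all(low >= ic_low_band[1] & low <= ic_low_band[2]),
    high_ic_in_band = all(high >= ic_high_band[1] & high <= ic_high_band[2]),
    freq_spread_ok = spread <= freq_spread_max,
    lengths_ok = all(lengths >= length_bounds[1] & lengths <= length_bounds[2]),
    reserved_pairs_observed = !(nrow(corpus) >= 1000L && any(unobserved))
  )

  structure(
    list(n_melodies = nrow(corpus), length_histogram = hist,
         target_frequencies = tf, freq_spread = spread, ic_table = ic_table,
         transition_matrix = tm, flags = flags,
         all_pass = all(flags)),
    class = "corpus_summary"
  )
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("<corpus_summary> %d melodies, lengths %d-%d\n", x$n_melodies,
              min(x$length_histogram$length), max(x$length_histogram$length)))
  cat("IC of reserved context-target pairs (bits):\n")
  print(as.data.frame(x$ic_table), row.names = FALSE)
  cat(sprintf("target-degree frequency spread: %.2f percentage points\n",
              x$freq_spread))
  cat("calibration:", if (x$all_pass) "PASS" else "FAIL", "\n")
  if (!x$all_pass) print(x$flags)
  invisible(x)
}

#' @rdname corpus_report
#' @param x A `corpus_summary`.
#' @param ... Unused.
#' @return For `glance()`: a one-row tibble with the headline calibration
#'   numbers and flags.
#' @method glance corpus_summary
#' @export
glance.corpus_summary <- function(x, ...) {
  tibble::tibble(
    n_melodies = x$n_melodies,
    ic_low_mean = mean(x$ic_table$ic_bits[x$ic_table$branch == "low_ic"]),
    ic_high_min = min(x$ic_table$ic_bits[x$ic_table$branch == "high_ic"]),
    freq_spread = x$freq_spread,
    min_length = min(x$length_histogram$length),
    max_length = max(x$length_histogram$length),
    all_pass = x$all_pass
  )
}
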