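#' Default artificial melodic grammar
#'
#' Constructs the first-order Markov grammar used to generate all stimuli.
#' Melodies are strings of scale degrees 1-7 (degree 7 is degree 1 one octave
#' up) assembled from five cells: a start cell, two information-content (IC)
#' cells, an intermediate cell and an end cell. Each IC cell is a fixed
#' context note followed by one of two target notes: the high-probability
#' target occurs with probability `p_high` (the low-IC target) and the other
#' with `1 - p_high` (the high-IC target). In the IC-alpha cell the context is
#' degree 3, the low-IC target ascends to 4 and the high-IC target descends
#' to 2; in the IC-beta cell the context is degree 5, the low-IC target
#' descends to 4 and the high-IC target ascends to 6.
#'
#' Global melodic constraints: no note repeats, no step larger than
#' `max_step` scale degrees, and the four context-target pairs
#' (5-4, 5-6, 3-4, 3-2) never occur outside the IC cells, so that corpus-level
#' conditional probabilities of the targets are controlled by the grammar.
#'
#' The filler-cell transition tables are package defaults calibrated so that
#' degrees 3 and 5 occur as contexts outside the IC cells about as often as
#' inside them. Pooled over a large corpus this puts the IC of the
#' high-probability transitions near 1 bit and of the low-probability
#' transitions near 5-6 bits, while keeping the overall frequencies of the
#' target degrees (2, 4, 6) within a few percentage points of each other.
#'
#' @param p_high Probability of the high-probability (low-IC) target within
#'   an IC cell. Default 0.95.
#' @param max_step Largest allowed interval between consecutive notes, in
#'   scale degrees. Default 4.
#' @param max_retries Number of whole-melody resampling attempts before a
#'   dead-end during constrained sampling becomes an error. Default 100.
#'
#' @return A `grammar_spec` object: a list with elements `cells` (named list
#'   of cell specifications), `module_orders` (the two admissible cell
#'   orderings for exposure melodies), `exposure_length` and `test_length`
#'   bounds, `test_cell_lengths` (cell length ranges for the shortened
#'   forced-choice grammar), `max_step`, and `max_retries`.
#'
#' @examples
#' spec <- default_grammar()
#' validate_grammar(spec)  # zero rows: the default is self-consistent
#' @export
default_grammar <- function(p_high = 0.95, max_step = 4L, max_retries = 100L) {
  stopifnot(p_high >= 0, p_high <= 1)

  trans_filler <- filler_transition_table()

  cells <- list(
    start = list(
      name = "start",
      length_range = c(1L, 3L),
      init = normalise(c(`1` = 0.30, `2` = 0.20, `3` = 0, `4` = 0.10,
                         `5` = 0, `6` = 0.20, `7` = 0.20)),
      trans = trans_filler,
      ic = NULL
    ),
    ic_alpha = ic_cell("ic_alpha", context = 3L, high_prob_target = 4L,
                       low_prob_target = 2L, p_high = p_high),
    intermediate = list(
      name = "intermediate",
      length_range = c(2L, 4L),
      init = normalise(c(`1` = 0.10, `2` = 0.20, `3` = 0.16, `4` = 0,
                         `5` = 0.20, `6` = 0.20, `7` = 0.14)),
      trans = trans_filler,
      ic = NULL
    ),
    ic_beta = ic_cell("ic_beta", context = 5L, high_prob_target = 4L,
                      low_prob_target = 6L, p_high = p_high),
    end = list(
      name = "end",
      length_range = c(2L, 3L),
      init = normalise(c(`1` = 0.06, `2` = 0.24, `3` = 0.16, `4` = 0,
                         `5` = 0.20, `6` = 0.24, `7` = 0.10)),
      trans = trans_filler,
      ic = NULL
    )
  )

  structure(
    list(
      cells = cells,
      module_orders = list(
        c("start", "ic_alpha", "intermediate", "ic_beta", "end"),
        c("start", "ic_beta", "intermediate", "ic_alpha", "end")
      ),
      exposure_length = c(9L, 14L),
      test_length = c(7L, 9L),
      test_cell_lengths = list(start = c(2L, 3L), end = c(3L, 4L)),
      max_step = as.integer(max_step),
      max_retries = as.integer(max_retries)
    ),
    class = "grammar_spec"
  )
}

ic_cell <- function(name, context, high_prob_target, low_prob_target, p_high) {
  trans <- matrix(0, 7, 7, dimnames = list(DEGREES, DEGREES))
  trans[context, high_prob_target] <- p_high
  trans[context, low_prob_target] <- 1 - p_high
  init <- setNames(numeric(7), DEGREES)
  init[context] <- 1
  list(
    name = name,
    length_range = c(2L, 2L),
    init = init,
    trans = trans,
    ic = list(context = context, high_prob_target = high_prob_target,
              low_prob_target = low_prob_target, p_high = p_high)
  )
}

normalise <- function(x) {
  out <- setNames(numeric(7), DEGREES)
  out[names(x)] <- x
  out / sum(out)
}

# Shared filler transition table (start / intermediate / end cells).
# Each row excludes repeats, steps > 4 scale degrees, and the four reserved
# context-target pairs; weights route mass toward degrees 2 and 6 (whose IC
# targets are rare) and keep visits to contexts 3 and 5 near one per melody.
filler_transition_table <- function() {
  w <- list(
    `1` = c(`2` = 0.45, `3` = 0.25, `4` = 0.05, `5` = 0.25),
    `2` = c(`1` = 0.10, `3` = 0.20, `4` = 0.05, `5` = 0.25, `6` = 0.40),
    `3` = c(`1` = 0.15, `5` = 0.25, `6` = 0.45, `7` = 0.15),
    `4` = c(`1` = 0.05, `2` = 0.35, `3` = 0.15, `5` = 0.15, `6` = 0.25,
            `7` = 0.05),
    `5` = c(`1` = 0.15, `2` = 0.45, `3` = 0.25, `7` = 0.15),
    `6` = c(`2` = 0.35, `3` = 0.20, `4` = 0.04, `5` = 0.26, `7` = 0.15),
    `7` = c(`3` = 0.25, `4` = 0.06, `5` = 0.32, `6` = 0.37)
  )
  m <- matrix(0, 7, 7, dimnames = list(DEGREES, DEGREES))
  for (from in names(w)) m[from, names(w[[from]])] <- w[[from]] / sum(w[[from]])
  m
}

#' Validate a grammar specification
#'
#' Checks every structural invariant of the grammar: row-stochastic transition
#' tables with no negative or missing entries, no repeated-note or
#' larger-than-`max_step` transitions, reserved context-target pairs confined
#' to the IC cells, well-formed IC cells (length 2, complementary branch
#' probabilities, targets one scale degree from the context), stochastic
#' initial distributions, and cell length ranges consistent with the declared
#' melody length bounds.
#'
#' Malformed probability rows are reported as violations, not raised as
#' errors, so a whole configuration can be audited in one pass.
#'
#' @param spec A `grammar_spec`, e.g. from [default_grammar()].
#' @param tol Numeric tolerance for row sums. Default 1e-9.
#'
#' @return A tibble of violations with columns `cell`, `rule`, and `detail`;
#'   zero rows if and only if the grammar is valid.
#' @examples
#' bad <- default_grammar()
#' bad$cells$start$trans[5, 6] <- 0.1  # reserved pair outside an IC cell
#' validate_grammar(bad)
#' @export
validate_grammar <- function(spec, tol = 1e-9) {
  stopifnot(inherits(spec, "grammar_spec"))
  v <- list()
  add <- function(cell, rule, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(cell = cell, rule = rule,
                                           detail = detail)
  }

  for (cell in spec$cells) {
    tr <- cell$trans
    if (any(!is.finite(tr)) || any(tr < 0, na.rm = TRUE)) {
      bad <- which(!is.finite(tr) | tr < 0, arr.ind = TRUE)
      for (k in seq_len(nrow(bad)))
        add(cell$name, "malformed probability",
            sprintf("row %d, col %d is negative or not finite",
                    bad[k, 1], bad[k, 2]))
      tr[!is.finite(tr)] <- 0
      tr[tr < 0] <- 0
    }
    rs <- rowSums(tr)
    for (i in which(rs > 0 & abs(rs - 1) > tol))
      add(cell$name, "row not stochastic",
          sprintf("row %d sums to %.6f", i, rs[i]))
    for (i in DEGREES) {
      if (tr[i, i] > 0)
        add(cell$name, "repeated note",
            sprintf("row %d assigns probability to itself", i))
      big <- which(tr[i, ] > 0 & abs(DEGREES - i) > spec$max_step)
      for (j in big)
        add(cell$name, "step too large",
            sprintf("row %d -> %d exceeds %d scale degrees",
                    i, j, spec$max_step))
    }
    if (is.null(cell$ic)) {
      for (k in seq_len(nrow(RESERVED_PAIRS))) {
        fr <- RESERVED_PAIRS[k, 1]; to <- RESERVED_PAIRS[k, 2]
        if (tr[fr, to] > 0)
          add(cell$name, "reserved pair outside IC cell",
              sprintf("row %d -> %d must only occur inside IC cells", fr, to))
      }
    } else {
      ic <- cell$ic
      if (!identical(cell$length_range, c(2L, 2L)))
        add(cell$name, "IC cell malformed", "IC cells must have length exactly 2")
      if (abs(ic$p_high + (1 - ic$p_high) - 1) > tol ||
          abs(sum(tr[ic$context, ]) - 1) > tol)
        add(cell$name, "IC cell malformed", "branch probabilities must sum to 1")
      if (abs(ic$high_prob_target - ic$context) != 1 ||
          abs(ic$low_prob_target - ic$context) != 1)
        add(cell$name, "IC cell malformed",
            "targets must be one scale degree from the context")
      if (!all(is_reserved_pair(rep(ic$context, 2),
                                c(ic$high_prob_target, ic$low_prob_target))))
        add(cell$name, "IC cell malformed",
            "context-target pairs must be the reserved pairs")
    }
    ini <- cell$init
    if (any(ini < 0) || abs(sum(ini) - 1) > tol)
      add(cell$name, "initial distribution not stochastic",
          sprintf("initial distribution sums to %.6f", sum(ini)))
  }

  len_tot <- Reduce(`+`, lapply(spec$cells, `[[`, "length_range"))
  if (!identical(as.integer(len_tot), as.integer(spec$exposure_length)))
    add("(grammar)", "length bounds inconsistent",
        sprintf("cell lengths give total %d-%d, declared %d-%d",
                len_tot[1], len_tot[2],
                spec$exposure_length[1], spec$exposure_length[2]))
  fc_tot <- spec$test_cell_lengths$start + c(2L, 2L) + spec$test_cell_lengths$end
  if (!identical(as.integer(fc_tot), as.integer(spec$test_length)))
    add("(grammar)", "length bounds inconsistent",
        sprintf("forced-choice cell lengths give total %d-%d, declared %d-%d",
                fc_tot[1], fc_tot[2], spec$test_length[1], spec$test_length[2]))

  if (length(v) == 0)
    tibble::tibble(cell = character(), rule = character(), detail = character())
  else dplyr::bind_rows(v)
}

#' @export
print.grammar_spec <- function(x, ...) {
  cat("<grammar_spec>\n")
  cat("  cells:", paste(names(x$cells), collapse = ", "), "\n")
  ic <- x$cells$ic_alpha$ic
  cat(sprintf("  p_high: %.2f  max_step: %d\n", ic$p_high, x$max_step))
  cat(sprintf("  exposure length: %d-%d, forced-choice length: %d-%d\n",
              x$exposure_length[1], x$exposure_length[2],
              x$test_length[1], x$test_length[2]))
  invisible(x)
}
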