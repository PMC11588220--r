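#' Plot the corpus transition surprisal matrix
#'
#' Heatmap of the information content (bits) of every observed first-order
#' transition, with the four designed context-target pairs outlined: solid
#' for the high-IC (0.05-branch) pairs, dashed for the low-IC (0.95-branch)
#' pairs.
#'
#' @param object A `transition_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transition_matrix
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- dplyr::filter(tidy(object), is.finite(.data$ic_bits))
  boxes <- tibble::tibble(
    context = c(5, 3, 5, 3), target = c(4, 4, 6, 2),
    branch = c("low-IC", "low-IC", "high-IC", "high-IC")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$context)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$ic_bits)) +
    ggplot2::geom_tile(data = boxes, fill = NA, colour = "black",
                       ggplot2::aes(linetype = .data$branch),
                       linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "IC (bits)") +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::scale_y_reverse(breaks = 1:7) +
    ggplot2::labs(x = "next degree", y = "context degree",
                  linetype = "designed pair") +
    ggplot2::theme_minimal()
}

#' Plot fixed-effect estimates of a fitted mixed model
#'
#' Dot-and-interval plot of the fixed-effect log-odds estimates with Wald
#' 95% confidence intervals, intercept omitted by default.
#'
#' @param object A `glmm_fit`.
#' @param intercept Include the intercept row. Default `FALSE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glmm_fit
#' @export
autoplot.glmm_fit <- function(object, intercept = FALSE, ...) {
  df <- tidy(object)
  if (!intercept) df <- dplyr::filter(df, .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log-odds estimate (95% CI)", y = NULL,
                  title = paste("Fixed effects:", object$task)) +
    ggplot2::theme_minimal()
}

#' Plot per-participant preference differences
#'
#' Jittered points of each participant's preference differences (high minus
#' low IC, and peak minus non-peak contour, in percentage points of accented
#' choices) with the group means.
#'
#' @param pref A tibble from [preference_differences()].
#' @return A ggplot object.
#' @export
plot_preference_differences <- function(pref) {
  long <- tidyr::pivot_longer(
    dplyr::filter(pref, !.data$incomplete),
    cols = c("delta_ic", "delta_peak"),
    names_to = "comparison", values_to = "delta"
  )
  long$comparison <- dplyr::recode(long$comparison,
                                   delta_ic = "high vs low IC",
                                   delta_peak = "peak vs non-peak")
  means <- long |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(delta = mean(.data$delta), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$comparison, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5) +
    ggplot2::geom_crossbar(data = means,
                           ggplot2::aes(ymin = .data$delta,
                                        ymax = .data$delta),
                           width = 0.4, colour = "black") +
    ggplot2::labs(x = NULL,
                  y = "difference in % accented chosen (pp)") +
    ggplot2::theme_minimal()
}

#' Plot the melody length distribution of a corpus
#'
#' @param object A `corpus_summary` from [corpus_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot corpus_summary
#' @export
autoplot.corpus_summary <- function(object, ...) {
  ggplot2::ggplot(object$length_histogram,
                  ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(breaks = function(l) seq(l[1], l[2])) +
    ggplot2::labs(x = "melody length (notes)", y = "melodies") +
    ggplot2::theme_minimal()
}
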