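#' Plot ancestral-state probabilities
#'
#' Stacked state-probability bars per node, ordered by node id; called states
#' (when present) are shown in the axis labels.
#'
#' @param object An `ancestral_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ancestral_table
#' @export
autoplot.ancestral_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, dplyr::all_of(c("p_absent", "p_pericentromeric", "p_distal")),
    names_to = "state", values_to = "probability", names_prefix = "p_"
  )
  long$state <- factor(long$state, levels = ancestral_states())
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$node),
                                     y = .data$probability,
                                     fill = .data$state)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_fill_manual(values = c(absent = "#f2d24b",
                                          pericentromeric = "#222222",
                                          distal = "#c23b22")) +
    ggplot2::labs(x = "node", y = "marginal probability", fill = "state") +
    ggplot2::theme_minimal()
}

#' Plot a correlated-evolution screen
#'
#' Per-segment likelihood-ratio statistic with the significance cut-off at
#' the screen's alpha (chi-square, df = 4).
#'
#' @param object A `pagel_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pagel_screen
#' @export
autoplot.pagel_screen <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  crit <- stats::qchisq(1 - alpha, df = 4)
  df <- dplyr::mutate(object,
                      segment = factor(.data$segment,
                                       levels = rev(.data$segment)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$segment,
                                   colour = .data$significant)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$statistic,
                                       yend = .data$segment)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = crit, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c23b22",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "LR statistic (df = 4)", y = NULL,
                  colour = paste0("p < ", alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a breakpoint co-occurrence summary
#'
#' @param object A `cooccurrence_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cooccurrence_summary
#' @export
autoplot.cooccurrence_summary <- function(object, ...) {
  df <- tibble::tibble(
    category = factor(c("undetermined", "neither", "cluster + centromere",
                        "other"),
                      levels = c("cluster + centromere", "neither", "other",
                                 "undetermined")),
    n = c(object$n_undetermined, object$n_neither, object$n_both,
          object$n_other)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "breakpoints") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang %||%
NULL
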