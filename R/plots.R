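# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline labs
#'   theme_minimal geom_col coord_flip geom_errorbarh
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Differences between methods against per-pair means, with the mean
#' difference and the 95% limits of agreement as horizontal lines.
#'
#' @param object A `dv_bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dv_bland_altman <- function(object, ...) {
  ggplot(object$data, aes(x = .data$pair_mean, y = .data$difference)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = object$mean_difference, linetype = "solid") +
    geom_hline(yintercept = object$loa_low, linetype = "dashed") +
    geom_hline(yintercept = object$loa_high, linetype = "dashed") +
    labs(
      x = "Mean of the two methods",
      y = "Difference (method A - method B)",
      title = "Bland-Altman agreement",
      subtitle = sprintf(
        "mean difference %.1f, 95%% LoA [%.1f, %.1f]",
        object$mean_difference, object$loa_low, object$loa_high
      )
    ) +
    theme_minimal()
}

#' @rdname autoplot.dv_bland_altman
#' @param x A `dv_bland_altman` object.
#' @export
plot_bland_altman <- function(x, ...) autoplot(x, ...)

#' Comparison overview plot
#'
#' Per-variable median intake under both methods, relevance-flagged
#' variables highlighted.
#'
#' @param object A `dv_comparison` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dv_comparison <- function(object, ...) {
  d <- object$paired %>%
    tidyr::pivot_longer(
      c("median_a", "median_b"),
      names_to = "method", values_to = "median_intake"
    ) %>%
    mutate(
      method = if_else(.data$method == "median_a", "method A", "method B"),
      flagged = if_else(
        !is.na(.data$relevant_difference) & .data$relevant_difference,
        "relevant difference", "no relevant difference"
      )
    )
  ggplot(d, aes(
    x = stats::reorder(.data$variable, .data$median_intake),
    y = .data$median_intake, fill = .data$method, alpha = .data$flagged
  )) +
    geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(
      values = c("relevant difference" = 1, "no relevant difference" = 0.45)
    ) +
    coord_flip() +
    labs(x = NULL, y = "Median intake per day", fill = NULL, alpha = NULL) +
    theme_minimal()
}
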