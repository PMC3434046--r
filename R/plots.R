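#' Plot a cutoff sweep
#'
#' Coverage (number of called orthologs) and, when available, the
#' false-positive rate as functions of the cutoff: the accuracy/coverage
#' trade-off the cutoff exists to expose.
#'
#' @param object An [omega_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot omega_sweep
#' @export
autoplot.omega_sweep <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(
      dplyr::any_of(c("n_called", "false_positive_rate")),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(metric = dplyr::recode(
      .data$metric,
      n_called = "predicted orthologs",
      false_positive_rate = "false positive rate"
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$omega, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = expression(Omega~"(quartet-score cutoff)"), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a conservation curve
#'
#' @param object A [conservation_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conservation_curve
#' @export
autoplot.conservation_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$n, .data$n_groups)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(breaks = object$n) +
    ggplot2::labs(
      x = "conserved in at least n species of the panel",
      y = "orthologous groups"
    ) +
    ggplot2::theme_minimal()
}

#' Group-size distribution of orthologous groups
#'
#' @param groups A [form_groups()] tibble.
#' @return A ggplot object (log-scaled counts of group sizes).
#' @export
plot_group_sizes <- function(groups) {
  ggplot2::ggplot(as_tibble(groups), ggplot2::aes(.data$size)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "group size (proteins)", y = "groups") +
    ggplot2::theme_minimal()
}
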