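#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an episode's order parameters over time
#'
#' Polarization and elongation versus time in two facets: the rapid
#' alignment jump, the elongation climb during steady navigation, and the
#' adjustment after arrival are all visible at a glance.
#'
#' @param object A `ps_episode` from [run_episode()] or [run_vicsek()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps_episode <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics[c("t", "polarization", "elongation")],
    -"t", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time step", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training learning curve
#'
#' Cumulative group reward, average policy entropy and average certainty
#' per training episode.
#'
#' @param object A `ps_fit` from [train_policy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$curve[c("episode", "total_reward", "avg_entropy", "avg_certainty")],
    -"episode", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$episode, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "training episode", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a policy's action probabilities
#'
#' The interpretable artifact of the model: one tile per (state, action)
#' pair colored by selection probability. Deterministic states appear as a
#' single bright tile in their row.
#'
#' @param object A `ps_policy_table` (or pass a `ps_policy` through
#'   [policy_table()] first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps_policy_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_deg, y = factor(.data$state),
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "steering angle (deg)", y = "percept state",
                  fill = "P(a | s)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ps_policy <- function(object, ...) autoplot(policy_table(object), ...)
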