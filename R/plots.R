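#' Plot group outcome trajectories in event time
#'
#' Simple trajectory plot of one outcome for each group, with the
#' ratification year (event time 0) marked.
#'
#' @param group_series Tibble from [aggregate_group()].
#' @param outcome Outcome column to plot.
#' @return A ggplot object.
#' @export
plot_group_series <- function(group_series, outcome = "log_smokers") {
  ggplot2::ggplot(
    group_series,
    ggplot2::aes(
      x = .data$event_time, y = .data[[outcome]],
      colour = .data$group, group = .data$group
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Years since ratification", y = outcome, colour = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a segmented trend fit
#'
#' Observed points, the fitted segmented trend, and the dashed continuation
#' of the pre-ratification trend over the post window (the counterfactual).
#'
#' @param object An `itsa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itsa_fit <- function(object, ...) {
  d <- tibble::tibble(
    event_time = object$design$event_time,
    observed = object$y,
    fitted = object$fitted
  )
  proj <- project_pre_trend(object, post_window_of(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$event_time)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 1.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2166ac") +
    ggplot2::geom_line(
      data = proj,
      ggplot2::aes(x = .data$event_time, y = .data$projected_log),
      colour = "#b2182b", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Years since ratification", y = object$outcome,
      title = sprintf(
        "%s, model %d (solid: fitted; dashed: pre-trend projection)",
        object$group, object$spec$model_id
      )
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a counterfactual comparison
#'
#' Projected (pre-trend) versus actual count trajectories over the post
#' window, from a one-row counterfactual result carrying its trajectory.
#'
#' @param object A result row from [counterfactual_from_fit()] or
#'   [averted()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_counterfactual <- function(object, ...) {
  traj <- attr(object, "trajectory")
  if (is.null(traj)) stop("no trajectory attached to this result", call. = FALSE)
  long <- tidyr::pivot_longer(traj, c("projected", "actual"),
    names_to = "series", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$event_time, y = .data$count,
    colour = .data$series, linetype = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Years since ratification", y = "Count",
      title = sprintf(
        "Averted at %d years: %.3g (%.1f%% of projected)",
        object$horizon, object$averted, object$averted_pct
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
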