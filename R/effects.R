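# delta-method helper: estimate and CI for 100 * g'beta on the HAC covariance
delta_effect <- function(fit, grad, quantity, conf_level, percent) {
  b <- full_beta(fit)
  v <- full_vcov(fit)
  est <- sum(grad * b)
  se <- sqrt(drop(t(grad) %*% v %*% grad))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- est - z * se
  hi <- est + z * se
  scale <- function(x) {
    if (percent == "log_points") 100 * x else (exp(x) - 1) * 100
  }
  tibble::tibble(
    group = fit$group,
    outcome = fit$outcome,
    model_id = fit$spec$model_id,
    quantity = quantity,
    estimate = scale(est),
    std.error = 100 * se,
    conf.low = scale(lo),
    conf.high = scale(hi)
  )
}

#' Average trend before ratification
#'
#' Mean annual slope of the fitted secular trend over the pre-ratification
#' rows: the derivative of `b1*T + b2*T^2 + b3*T^3` with respect to `T`,
#' averaged over the pre-period values of `T`, expressed in percent per year
#' (outcomes are logs, so 100 log-points approximate relative percentage
#' change). The CI is by the delta method on the HAC covariance.
#'
#' @param fit A selected `itsa_fit`.
#' @param conf_level Confidence level (default 0.95).
#' @param percent `"log_points"` (default, 100 x log-points) or `"exact"`
#'   (`(exp(d)-1)*100`).
#' @return One-row tibble: `group`, `outcome`, `model_id`, `quantity`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high` (all in %).
#' @export
avg_pre_trend <- function(fit, conf_level = 0.95,
                          percent = c("log_points", "exact")) {
  percent <- match.arg(percent)
  tt <- fit$design$T[fit$design$event_time < 0]
  grad <- stats::setNames(numeric(7), itsa_terms())
  grad["T"] <- 1
  grad["T2"] <- 2 * mean(tt)
  grad["T3"] <- 3 * mean(tt^2)
  delta_effect(fit, grad, "avg_pre_trend", conf_level, percent)
}

#' Average annual change in trend after ratification
#'
#' Mean annual slope of the post-ratification trend-change component: the
#' derivative of `b5*I + b6*I^2` with respect to `I`, averaged over the
#' post-period grid of `I`. The ratification year itself belongs to the post
#' period (`I = 0` at event time 0), so the default grid is `I = 0..horizon`;
#' set `grid_from = 1` to average from the first full post year instead.
#'
#' @inheritParams avg_pre_trend
#' @param horizon Last post year in the averaging grid (default: the fit's
#'   post window).
#' @param grid_from First value of `I` in the grid, 0 (default) or 1.
#' @return One-row tibble as in [avg_pre_trend()].
#' @export
avg_trend_change <- function(fit, conf_level = 0.95, horizon = NULL,
                             grid_from = 0,
                             percent = c("log_points", "exact")) {
  percent <- match.arg(percent)
  if (is.null(horizon)) horizon <- post_window_of(fit)
  ii <- seq(grid_from, horizon)
  grad <- stats::setNames(numeric(7), itsa_terms())
  grad["X_I"] <- 1
  grad["X_I2"] <- 2 * mean(ii)
  delta_effect(fit, grad, "avg_trend_change", conf_level, percent)
}

#' Cumulative effect at a horizon
#'
#' Difference between the fitted post-ratification outcome and the
#' counterfactual continuation of the secular trend, evaluated `horizon`
#' years after ratification: `b4 + b5*h + b6*h^2` on the log scale (the
#' level change conditional on `I = h`), expressed in percent.
#'
#' @inheritParams avg_pre_trend
#' @param horizon Years after ratification (default 10); must not exceed the
#'   fit's post window.
#' @return One-row tibble as in [avg_pre_trend()].
#' @export
cumulative_effect <- function(fit, horizon = 10, conf_level = 0.95,
                              percent = c("log_points", "exact")) {
  percent <- match.arg(percent)
  if (horizon > post_window_of(fit)) {
    stop("horizon exceeds the fitted post window", call. = FALSE)
  }
  grad <- stats::setNames(numeric(7), itsa_terms())
  grad["X"] <- 1
  grad["X_I"] <- horizon
  grad["X_I2"] <- horizon^2
  delta_effect(fit, grad, "cumulative_effect", conf_level, percent)
}

#' All effect estimates for one fit
#'
#' Stacks [avg_pre_trend()], [avg_trend_change()] and [cumulative_effect()]
#' into the layout of a results table row (group x outcome with trend change
#' and cumulative effect plus the selected model id).
#'
#' @inheritParams cumulative_effect
#' @return A three-row tibble.
#' @export
itsa_effects <- function(fit, horizon = 10, conf_level = 0.95,
                         percent = c("log_points", "exact")) {
  percent <- match.arg(percent)
  dplyr::bind_rows(
    avg_pre_trend(fit, conf_level, percent),
    avg_trend_change(fit, conf_level, horizon = horizon, percent = percent),
    cumulative_effect(fit, horizon, conf_level, percent)
  )
}
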