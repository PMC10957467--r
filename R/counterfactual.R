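#' Project the pre-ratification trend over the post window
#'
#' Evaluates only the secular-trend part of a fitted model
#' (`b0 + b1*T + b2*T^2 + b3*T^3`) at the post-period time values and
#' exponentiates, giving the counterfactual count trajectory had the
#' pre-ratification trend continued. Only meaningful for log-count outcomes.
#'
#' @param fit A selected `itsa_fit` on a log-count outcome.
#' @param horizon Years after ratification (default 10); must not exceed the
#'   fit's post window.
#' @return A tibble with `event_time` (0..horizon), `T`, `projected_log`,
#'   `projected` (counts).
#' @export
project_pre_trend <- function(fit, horizon = 10) {
  if (horizon > post_window_of(fit)) {
    stop("horizon exceeds the fitted post window", call. = FALSE)
  }
  b <- full_beta(fit)
  d <- fit$design[fit$design$event_time >= 0 & fit$design$event_time <= horizon, ]
  proj_log <- b["(Intercept)"] + b["T"] * d$T + b["T2"] * d$T^2 + b["T3"] * d$T^3
  tibble::tibble(
    event_time = d$event_time, T = d$T,
    projected_log = unname(proj_log),
    projected = exp(unname(proj_log))
  )
}

#' Averted count from projected and actual trajectories
#'
#' Compares the counterfactual (projected) and actual count trajectories over
#' the post window. In `at_horizon` mode (default) the averted count is the
#' difference at the final year — a stock difference, consistent with pairing
#' an averted count with the cumulative effect percentage at the same
#' horizon. In `cumulative_person_years` mode it is the sum of the yearly
#' differences over the `horizon` years after ratification (event times
#' 1..horizon; the ratification-year stock itself is not double counted).
#'
#' @param projected,actual Equal-length count trajectories covering event
#'   times 0..horizon.
#' @param horizon Years after ratification.
#' @param mode `"at_horizon"` (default) or `"cumulative_person_years"`.
#' @param group,outcome Optional labels carried into the result.
#' @return A one-row tibble of class `itsa_counterfactual_row`:
#'   `projected_count`, `actual_count` (at the reference), `averted`,
#'   `averted_pct`, `horizon`, `mode`; the paired trajectory is attached as
#'   attribute `"trajectory"`.
#' @export
averted <- function(projected, actual, horizon,
                    mode = c("at_horizon", "cumulative_person_years"),
                    group = NA_character_, outcome = NA_character_) {
  mode <- match.arg(mode)
  if (length(projected) != length(actual)) {
    stop("projected and actual trajectories differ in length", call. = FALSE)
  }
  if (length(projected) != horizon + 1) {
    stop("trajectories must cover event times 0..horizon", call. = FALSE)
  }
  if (any(projected <= 0)) stop("projected counts must be positive", call. = FALSE)
  if (mode == "at_horizon") {
    p <- projected[horizon + 1]
    a <- actual[horizon + 1]
  } else {
    p <- sum(projected[-1])
    a <- sum(actual[-1])
  }
  out <- tibble::tibble(
    group = group, outcome = outcome, horizon = as.integer(horizon), mode = mode,
    projected_count = p, actual_count = a,
    averted = p - a, averted_pct = 100 * (p - a) / p
  )
  attr(out, "trajectory") <- tibble::tibble(
    event_time = 0:horizon, projected = projected, actual = actual
  )
  out
}

#' Counterfactual averted counts from a fit
#'
#' Convenience wrapper: projects the pre-ratification trend from a fitted
#' model and compares it against the actual trajectory. `actual = "observed"`
#' uses the observed counts the model was fitted to; `actual = "fitted"` uses
#' the model's own fitted values, in which case the averted percentage at the
#' horizon equals `-(exp(D) - 1)*100` of the fit's log-scale cumulative
#' effect `D` exactly.
#'
#' @inheritParams project_pre_trend
#' @param actual Source of the actual trajectory.
#' @param mode See [averted()].
#' @return A one-row tibble, see [averted()].
#' @export
counterfactual_from_fit <- function(fit, horizon = 10,
                                    actual = c("observed", "fitted"),
                                    mode = c("at_horizon", "cumulative_person_years")) {
  actual <- match.arg(actual)
  mode <- match.arg(mode)
  proj <- project_pre_trend(fit, horizon)
  post <- fit$design$event_time >= 0 & fit$design$event_time <= horizon
  act_log <- if (actual == "observed") fit$y[post] else fit$fitted[post]
  averted(proj$projected, exp(act_log), horizon,
    mode = mode, group = fit$group, outcome = fit$outcome
  )
}

#' Reassign a donor group's relative effect to other groups
#'
#' Scenario analysis: applies the donor group's averted percentage to each
#' target group's projected count, answering "had every group experienced the
#' donor's relative decline, how many smokers would have been averted".
#'
#' @param group_results A tibble of counterfactual rows ([averted()] /
#'   [counterfactual_from_fit()] stacked), one per group.
#' @param donor_group Group label whose `averted_pct` is applied.
#' @return `group_results` with `scenario_averted` and `scenario_pct`
#'   columns (the donor's own row reproduces its actual averted count).
#' @export
scenario_reassign <- function(group_results, donor_group) {
  donor <- group_results[group_results$group == donor_group, , drop = FALSE]
  if (nrow(donor) != 1 || is.na(donor$averted_pct)) {
    stop("no estimate available for donor group '", donor_group, "'", call. = FALSE)
  }
  dplyr::mutate(
    group_results,
    scenario_pct = donor$averted_pct,
    scenario_averted = .data$projected_count * donor$averted_pct / 100
  )
}
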