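#' Run the full event-time analysis pipeline
#'
#' Orchestrates the whole analysis: group countries, realign each country's
#' series to event time around its own ratification year, aggregate counts
#' within groups, fit the five segmented trend models per group and outcome,
#' select by AIC, convert the selected fits into trend-change and
#' cumulative-effect estimates, project pre-ratification trends to quantify
#' averted smokers (and additional quitters from the former-smoker series),
#' and optionally bootstrap countries for percentile intervals. Identical
#' inputs and seed give identical outputs.
#'
#' @param panel Validated panel tibble ([read_panel()] / [simulate_cohort()]).
#' @param meta Country metadata tibble.
#' @param grouping_scheme One of `"world"`, `"income"`, `"tax"`,
#'   `"country"`, or a prebuilt membership tibble from [build_grouping()].
#' @param window A [window_config()].
#' @param outcomes Outcome columns to model.
#' @param horizon Horizon in years for cumulative effects and averted counts.
#' @param hac_lags Newey-West truncation lag (default automatic).
#' @param aic_window `"full"` or `"pre"`, see [select_model()].
#' @param model_ids Candidate models (default 1:5).
#' @param averted_mode See [averted()].
#' @param bootstrap `NULL`, or a [bootstrap_config()] to add country-
#'   bootstrap intervals for the cumulative effect on each outcome.
#' @param exclude Passed to [build_grouping()] when `grouping_scheme` is a
#'   scheme name.
#' @param out_dir Optional directory; when given, all tables, the run log
#'   and a JSON summary are written there.
#' @return A list of class `itsa_run`: `group_series`, `fits` (selected, per
#'   group x outcome), `effects`, `descriptives`, `counterfactual`,
#'   `bootstrap` (or NULL), `log`, `config`.
#' @export
run_pipeline <- function(panel, meta,
                         grouping_scheme = "world",
                         window = window_config(),
                         outcomes = c("log_smokers", "log_prevalence", "log_quit_ratio"),
                         horizon = 10,
                         hac_lags = NULL,
                         aic_window = "full",
                         model_ids = 1:5,
                         averted_mode = "at_horizon",
                         bootstrap = NULL,
                         exclude = "CHN",
                         out_dir = NULL) {
  if (horizon > window$post_window) {
    stop("horizon exceeds the post window", call. = FALSE)
  }
  validate_panel(panel)
  grouping <- if (is.data.frame(grouping_scheme)) {
    grouping_scheme
  } else {
    build_grouping(meta, grouping_scheme,
      exclude = exclude,
      last_data_year = max(panel$year), post_window = window$post_window
    )
  }
  exclusions <- attr(grouping, "exclusions")
  if (is.null(exclusions)) {
    exclusions <- tibble::tibble(country_id = character(), reason = character())
  }
  run_log <- dplyr::bind_rows(
    tibble::tibble(
      country_id = grouping$country_id, status = "included",
      detail = grouping$group
    ),
    tibble::tibble(
      country_id = exclusions$country_id, status = "excluded",
      detail = exclusions$reason
    )
  )

  events <- realign(panel, dplyr::semi_join(meta, grouping, by = "country_id"), window)
  gs <- aggregate_group(events, grouping)

  cells <- tidyr::expand_grid(group = unique(gs$group), outcome = outcomes)
  fits <- purrr::pmap(cells, function(group, outcome) {
    fit <- select_model(
      fit_itsa_models(gs[gs$group == group, ], outcome, model_ids, hac_lags),
      aic_window = aic_window
    )
    fit
  })
  names(fits) <- paste(cells$group, cells$outcome, sep = ".")

  effects <- dplyr::bind_rows(purrr::map(fits, itsa_effects, horizon = horizon))

  descriptives <- dplyr::bind_rows(purrr::map(
    split(gs, gs$group),
    function(g) {
      at <- function(t, col) g[[col]][g$event_time == t]
      tibble::tibble(
        group = g$group[1],
        smokers_at_ratification = at(0, "smokers_u25"),
        former_at_ratification = at(0, "former_45_59"),
        ever_at_ratification = at(0, "ever_45_59"),
        quit_ratio_at_ratification = quit_ratio(
          at(0, "former_45_59"), at(0, "ever_45_59")
        ),
        prevalence_pre = 100 * exp(at(-window$pre_window, "log_prevalence")),
        prevalence_at_ratification = 100 * exp(at(0, "log_prevalence")),
        prevalence_post = 100 * exp(at(window$post_window, "log_prevalence"))
      )
    }
  ))

  cf_outcomes <- intersect(c("log_smokers", "log_former"), outcomes)
  if ("log_former" %in% names(gs) && !"log_former" %in% cf_outcomes) {
    cf_outcomes <- c(cf_outcomes, "log_former")
  }
  counterfactual <- dplyr::bind_rows(purrr::map(
    unique(gs$group),
    function(group) {
      dplyr::bind_rows(purrr::map(cf_outcomes, function(oc) {
        key <- paste(group, oc, sep = ".")
        fit <- if (key %in% names(fits)) {
          fits[[key]]
        } else {
          select_model(
            fit_itsa_models(gs[gs$group == group, ], oc, model_ids, hac_lags),
            aic_window = aic_window
          )
        }
        counterfactual_from_fit(fit, horizon, mode = averted_mode)
      }))
    }
  ))

  boot <- NULL
  if (!is.null(bootstrap)) {
    boot <- dplyr::bind_rows(purrr::map(outcomes, function(oc) {
      res <- bootstrap_pipeline(
        panel, meta, grouping, window,
        statistic = stat_cumulative_effect(oc, horizon, model_ids, hac_lags),
        config = bootstrap
      )
      res$outcome <- oc
      res
    }))
  }

  run <- structure(
    list(
      group_series = gs, fits = fits, effects = effects,
      descriptives = descriptives, counterfactual = counterfactual,
      bootstrap = boot, log = run_log,
      config = list(
        grouping_scheme = if (is.data.frame(grouping_scheme)) "custom" else grouping_scheme,
        window = window, outcomes = outcomes, horizon = horizon,
        hac_lags = hac_lags, aic_window = aic_window,
        model_ids = model_ids, averted_mode = averted_mode,
        exclude = exclude
      )
    ),
    class = "itsa_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write all run artifacts to a directory
#'
#' Emits `group_series.csv`, `effects.csv`, `descriptives.csv`,
#' `counterfactual.csv`, `model_selection.csv`, `run_log.csv`,
#' `bootstrap.csv` (when present) and a machine-readable `summary.json`.
#'
#' @param run An `itsa_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f), progress = FALSE)
  w(run$group_series, "group_series.csv")
  w(run$effects, "effects.csv")
  w(run$descriptives, "descriptives.csv")
  w(run$counterfactual, "counterfactual.csv")
  sel <- dplyr::bind_rows(purrr::imap(run$fits, function(f, key) {
    s <- f$selection
    s$cell <- key
    s
  }))
  w(sel, "model_selection.csv")
  w(run$log, "run_log.csv")
  if (!is.null(run$bootstrap)) w(run$bootstrap, "bootstrap.csv")
  jsonlite::write_json(
    list(
      effects = run$effects, counterfactual = run$counterfactual,
      descriptives = run$descriptives
    ),
    file.path(out_dir, "summary.json"),
    dataframe = "rows", digits = NA, auto_unbox = TRUE
  )
  invisible(out_dir)
}

#' @export
print.itsa_run <- function(x, ...) {
  cat(sprintf(
    "Event-time analysis run: %d group(s), outcomes: %s\n",
    length(unique(x$group_series$group)), paste(x$config$outcomes, collapse = ", ")
  ))
  cat("Effects (percent):\n")
  print(x$effects, ...)
  invisible(x)
}

#' Tidy an analysis run
#'
#' @param x An `itsa_run`.
#' @param ... Unused.
#' @return The effects table (one row per group x outcome x quantity).
#' @export
tidy.itsa_run <- function(x, ...) x$effects

#' Glance at an analysis run
#'
#' @param x An `itsa_run`.
#' @param ... Unused.
#' @return One row per group x outcome with the selected model and AIC.
#' @export
glance.itsa_run <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$fits, function(f) {
    g <- glance(f)
    g$group <- f$group
    g$outcome <- f$outcome
    dplyr::relocate(g, "group", "outcome")
  }))
}
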