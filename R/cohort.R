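#' Event-time window configuration
#'
#' The analysis window around each country's ratification year: `pre_window`
#' years before (default 10, sensitivity option 13) and `post_window` years
#' after (default 10), with event time t = 0 at the ratification year itself.
#' `alt_start_year` implements the sensitivity rule of treating countries
#' that ratified before the treaty became binding as ratifying in that year
#' (set it to 2005 to reproduce that analysis).
#'
#' @param pre_window Years before ratification (>= 3).
#' @param post_window Years after ratification (>= 1).
#' @param alt_start_year Optional calendar year; ratification years earlier
#'   than this are moved up to it before realignment.
#' @return A list of class `window_config`.
#' @export
window_config <- function(pre_window = 10, post_window = 10,
                          alt_start_year = NULL) {
  stopifnot(pre_window >= 3, post_window >= 1)
  structure(
    list(
      pre_window = as.integer(pre_window),
      post_window = as.integer(post_window),
      alt_start_year = alt_start_year
    ),
    class = "window_config"
  )
}

#' Realign country series to event time
#'
#' Centers each country's series on its own ratification year: event time
#' `t = calendar_year - ratification_year`, retained over
#' `[-pre_window, +post_window]`. Every member country must cover the full
#' window in every age band; missing years are an error (no interpolation).
#'
#' @param panel Validated panel tibble ([read_panel()]).
#' @param meta Country metadata with `country_id` and `ratification_year`;
#'   countries with no ratification year are dropped silently (they are
#'   excluded with a reason by [build_grouping()]).
#' @param window A [window_config()].
#' @return A tibble of event series: `country_id`, `event_time`,
#'   `calendar_year`, `age_band`, and the four count columns.
#' @export
realign <- function(panel, meta, window = window_config()) {
  rat <- dplyr::filter(meta, !is.na(.data$ratification_year))
  rat <- dplyr::select(rat, "country_id", "ratification_year")
  if (!is.null(window$alt_start_year)) {
    rat$ratification_year <- pmax(rat$ratification_year, window$alt_start_year)
  }
  ev <- dplyr::inner_join(panel, rat, by = "country_id")
  ev <- dplyr::mutate(ev, event_time = .data$year - .data$ratification_year)
  ev <- dplyr::filter(
    ev,
    .data$event_time >= -window$pre_window,
    .data$event_time <= window$post_window
  )

  expected <- window$pre_window + window$post_window + 1L
  cov <- dplyr::summarise(
    dplyr::group_by(ev, .data$country_id, .data$age_band),
    n = dplyr::n(), .groups = "drop"
  )
  # a country absent from the panel entirely is also incomplete coverage
  absent <- setdiff(rat$country_id, unique(ev$country_id))
  bad <- cov[cov$n != expected, , drop = FALSE]
  if (nrow(bad) || length(absent)) {
    offender <- if (nrow(bad)) bad$country_id[1] else absent[1]
    have <- ev$year[ev$country_id == offender]
    ry <- rat$ratification_year[rat$country_id == offender]
    want <- (ry - window$pre_window):(ry + window$post_window)
    stop(
      sprintf(
        "incomplete window coverage for %s: missing year(s) %s", offender,
        paste(setdiff(want, have), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  ev <- dplyr::select(
    ev, "country_id", "event_time",
    calendar_year = "year", "age_band", "current_smokers", "population",
    "former_smokers", "ever_smokers"
  )
  dplyr::arrange(ev, .data$country_id, .data$age_band, .data$event_time)
}

#' Former-to-ever smoker quit ratio
#'
#' The cessation measure: former smokers divided by ever smokers
#' (former + current) in the same age band.
#'
#' @param former,ever Counts (vectors recycle as usual).
#' @return `former / ever`, in (0, 1].
#' @export
#' @examples
#' quit_ratio(79e6, 231e6) # ~0.34
quit_ratio <- function(former, ever) {
  if (any(ever <= 0)) stop("quit ratio undefined: ever smokers must be > 0", call. = FALSE)
  if (any(former > ever)) stop("former smokers exceed ever smokers", call. = FALSE)
  if (any(former < 0)) stop("negative former smoker count", call. = FALSE)
  former / ever
}

#' Aggregate event series into group series
#'
#' Sums counts across the member countries of each group at each event time
#' (membership constant across the window), then derives the three log
#' outcomes from the sums: log number of current smokers aged 10-24, log
#' prevalence aged 10-24 (ratio of summed smokers to summed population), and
#' log quit ratio aged 45-59 (ratio of summed former to summed ever). Ratios
#' of sums, never means of ratios. Zero aggregates would give infinite logs
#' and are an error.
#'
#' @param events Event series from [realign()].
#' @param grouping Membership tibble from [build_grouping()].
#' @return A tibble with one row per (group, event_time): summed counts
#'   `smokers_u25`, `population_u25`, `former_45_59`, `ever_45_59`, outcomes
#'   `log_smokers`, `log_prevalence`, `log_quit_ratio`, plus `log_former`
#'   (used by the additional-quitters counterfactual).
#' @export
aggregate_group <- function(events, grouping) {
  missing <- setdiff(grouping$country_id, unique(events$country_id))
  if (length(missing)) {
    stop(
      "group member(s) missing from event series: ",
      paste(utils::head(missing, 10), collapse = ", "),
      call. = FALSE
    )
  }
  joined <- dplyr::inner_join(grouping, events, by = "country_id",
    relationship = "many-to-many"
  )
  young <- dplyr::filter(joined, .data$age_band == age_bands()[1])
  old <- dplyr::filter(joined, .data$age_band == age_bands()[2])
  sum_y <- dplyr::summarise(
    dplyr::group_by(young, .data$group, .data$event_time),
    smokers_u25 = sum(.data$current_smokers),
    population_u25 = sum(.data$population),
    .groups = "drop"
  )
  sum_o <- dplyr::summarise(
    dplyr::group_by(old, .data$group, .data$event_time),
    former_45_59 = sum(.data$former_smokers),
    ever_45_59 = sum(.data$ever_smokers),
    .groups = "drop"
  )
  gs <- dplyr::full_join(sum_y, sum_o, by = c("group", "event_time"))

  n_t <- tapply(gs$event_time, gs$group, length)
  if (length(unique(n_t)) > 1) {
    stop("groups cover different numbers of event times; membership must be constant",
      call. = FALSE
    )
  }
  zero <- gs$smokers_u25 <= 0 | gs$population_u25 <= 0 |
    gs$former_45_59 <= 0 | gs$ever_45_59 <= 0
  if (any(zero, na.rm = TRUE) || anyNA(zero)) {
    stop("zero or missing aggregate count; log outcomes undefined", call. = FALSE)
  }
  gs <- dplyr::mutate(
    gs,
    log_smokers = log(.data$smokers_u25),
    log_prevalence = log(.data$smokers_u25 / .data$population_u25),
    log_quit_ratio = log(quit_ratio(.data$former_45_59, .data$ever_45_59)),
    log_former = log(.data$former_45_59)
  )
  dplyr::arrange(gs, .data$group, .data$event_time)
}

#' Tidy export of a group series
#'
#' @param group_series Tibble from [aggregate_group()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_group_series <- function(group_series, path) {
  readr::write_csv(group_series, path, progress = FALSE)
  invisible(path)
}
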