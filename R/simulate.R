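#' Parameters for one simulated country
#'
#' The generator mirrors the segmented-trend model the analysis fits: on the
#' log scale, current smokers aged 10-24 follow a polynomial secular trend
#' plus a level/slope/quadratic break switched on at the country's own
#' ratification year, with stationary AR(1) Gaussian noise. Population grows
#' geometrically; former and ever smokers aged 45-59 follow a log-linear quit
#' ratio with an optional post-ratification drift.
#'
#' @param country_id Country label.
#' @param ratification_year Calendar year of ratification.
#' @param baseline_log_smokers Log current smokers at the window origin.
#' @param pre_trend Numeric length 3: secular trend coefficients
#'   (b1, b2, b3) per year on the log scale.
#' @param level_change,slope_change,quad_change Break parameters (log-points,
#'   log-points/yr, log-points/yr^2), active from the ratification year.
#' @param noise_sd Stationary sd of the AR(1) log-scale noise.
#' @param ar1_rho AR(1) coefficient, in [0, 1).
#' @param baseline_prevalence Smoking prevalence aged 10-24 at the window
#'   origin; sets the population level.
#' @param pop_growth Annual population growth rate.
#' @param quit_baseline Quit ratio (former/ever) at the window origin.
#' @param quit_trend Annual secular drift of the log quit ratio.
#' @param quit_drift Post-ratification additional drift of the log quit
#'   ratio per year since ratification.
#' @param baseline_ever Ever smokers aged 45-59 at the window origin.
#' @param ever_growth Annual growth of the ever-smoker count.
#' @return A list of class `sim_country_params`.
#' @export
sim_country_params <- function(country_id = "SIM",
                               ratification_year = 2005,
                               baseline_log_smokers = log(2e5),
                               pre_trend = c(-0.01, 0, 0),
                               level_change = 0, slope_change = 0,
                               quad_change = 0,
                               noise_sd = 0.02, ar1_rho = 0.5,
                               baseline_prevalence = 0.15,
                               pop_growth = 0.01,
                               quit_baseline = 0.30, quit_trend = 0.005,
                               quit_drift = 0,
                               baseline_ever = 3 * exp(baseline_log_smokers),
                               ever_growth = 0.01) {
  stopifnot(
    length(pre_trend) == 3, ar1_rho >= 0, ar1_rho < 1, noise_sd >= 0,
    baseline_prevalence > 0, baseline_prevalence < 1,
    quit_baseline > 0, quit_baseline <= 1
  )
  structure(
    list(
      country_id = country_id, ratification_year = as.integer(ratification_year),
      baseline_log_smokers = baseline_log_smokers, pre_trend = pre_trend,
      level_change = level_change, slope_change = slope_change,
      quad_change = quad_change, noise_sd = noise_sd, ar1_rho = ar1_rho,
      baseline_prevalence = baseline_prevalence, pop_growth = pop_growth,
      quit_baseline = quit_baseline, quit_trend = quit_trend,
      quit_drift = quit_drift, baseline_ever = baseline_ever,
      ever_growth = ever_growth
    ),
    class = "sim_country_params"
  )
}

# noiseless log-smoker curve and its pre-trend-only counterpart, on a year grid
sim_mean_curves <- function(params, years, pre_window = 10) {
  origin <- params$ratification_year - pre_window
  s <- years - origin + 1 # T = 1 at the window start, as in the design matrix
  b <- params$pre_trend
  pre <- params$baseline_log_smokers + b[1] * s + b[2] * s^2 + b[3] * s^3
  ii <- pmax(years - params$ratification_year, 0)
  xx <- as.numeric(years >= params$ratification_year)
  brk <- xx * (params$level_change + params$slope_change * ii +
    params$quad_change * ii^2)
  list(pre = pre, full = pre + brk, s = s, I = ii, X = xx)
}

ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0) {
    return(numeric(n))
  }
  z <- stats::rnorm(n)
  e <- numeric(n)
  e[1] <- sd * z[1]
  innov_sd <- sd * sqrt(1 - rho^2)
  for (t in seq_len(n)[-1]) e[t] <- rho * e[t - 1] + innov_sd * z[t]
  e
}

#' Simulate one country's panel rows
#'
#' @param params A [sim_country_params()].
#' @param years Calendar years to generate (must cover the analysis window).
#' @param seed Optional seed (same seed, identical panel).
#' @param pre_window Pre-ratification window length the trend origin is
#'   anchored to (default 10).
#' @param round_counts Round counts to integers (default TRUE; turn off for
#'   exact noiseless ground-truth checks).
#' @return A panel tibble (both age bands) accepted by [validate_panel()].
#' @export
simulate_country <- function(params, years, seed = NULL, pre_window = 10,
                             round_counts = TRUE) {
  with_seed_(seed, {
    n <- length(years)
    curves <- sim_mean_curves(params, years, pre_window)
    log_smk <- curves$full + ar1_noise(n, params$noise_sd, params$ar1_rho)
    smokers <- exp(log_smk)
    s0 <- years - (params$ratification_year - pre_window)
    population <- exp(params$baseline_log_smokers) / params$baseline_prevalence *
      (1 + params$pop_growth)^s0
    if (any(smokers >= population)) {
      stop("implied prevalence outside (0,1); adjust baseline_prevalence or trends",
        call. = FALSE
      )
    }
    ever <- params$baseline_ever * (1 + params$ever_growth)^s0
    log_q <- log(params$quit_baseline) + params$quit_trend * s0 +
      curves$X * params$quit_drift * curves$I +
      ar1_noise(n, params$noise_sd / 2, params$ar1_rho)
    if (any(log_q > 0)) {
      stop("implied quit ratio above 1; adjust quit parameters", call. = FALSE)
    }
    former <- exp(log_q) * ever
    rnd <- if (round_counts) round else identity
    young <- tibble::tibble(
      country_id = params$country_id, year = as.integer(years),
      age_band = age_bands()[1],
      current_smokers = rnd(smokers), population = rnd(population),
      former_smokers = NA_real_, ever_smokers = NA_real_
    )
    old <- tibble::tibble(
      country_id = params$country_id, year = as.integer(years),
      age_band = age_bands()[2],
      current_smokers = rnd(ever - former), population = rnd(2 * ever),
      former_smokers = rnd(former), ever_smokers = rnd(ever)
    )
    validate_panel(dplyr::bind_rows(young, old))
  })
}

# ratification years 2004-2010, median 2005, mirroring the observed spread
sample_ratification_years <- function(n) {
  sample(2004:2010, n,
    replace = TRUE,
    prob = c(0.25, 0.30, 0.15, 0.10, 0.08, 0.07, 0.05)
  )
}

default_income_effects <- function() {
  # per-year post slope changes on the log scale, one per income group;
  # magnitudes in the band observed for annual trend changes (-6 to +1.3 %/yr)
  c("high" = 0.001, "upper-middle" = -0.033, "lower-middle" = -0.008, "low" = -0.06)
}

#' Simulate a full multi-country cohort with known ground truth
#'
#' Generates the three-table input set the readers accept unchanged (panel,
#' country metadata, and a ground-truth table per group). Countries within a
#' group share the secular-trend coefficients and the break parameters —
#' baselines, populations and noise vary per country — so the group-level log
#' aggregate is exactly the shared polynomial plus the shared break and the
#' true effects are available in closed form.
#'
#' Presets: `"world"` (one shared effect profile, default a slope-only break
#' of -1.5%/yr giving a cumulative effect of -15% at 10 years), `"null"`
#' (all break parameters zero), `"income-groups"` (four income groups with
#' group-specific slope changes), `"tax-split"` (high-tax-change countries,
#' about 14% of those with tax data, receive roughly twice the slope change
#' of low-tax-change countries).
#'
#' @param n_countries Number of countries (default 170).
#' @param preset Scenario preset, see Details.
#' @param effect Named list overriding the break profile:
#'   `level`, `slope`, `quad` (log-points, /yr, /yr^2). Applied to all
#'   countries for `"world"`/`"null"`.
#' @param pre_trend Shared secular trend coefficients (b1, b2, b3).
#' @param noise_sd,ar1_rho Noise parameters passed to every country.
#' @param years Calendar years generated (default 1994-2020, covering a
#'   10/10 window for all ratification years 2004-2010).
#' @param horizon Horizon (years) at which the true cumulative effect and
#'   averted counts are evaluated (default 10).
#' @param include_china Add a `"CHN"` row (with a positive post-trend, kept
#'   out of world groupings by default configuration downstream).
#' @param seed Seed for the whole cohort draw.
#' @param round_counts Passed to [simulate_country()].
#' @return A list of class `itsa_sim`: `panel`, `meta`, `truth` (per-group
#'   true average trend change %, cumulative effect % at `horizon`, averted
#'   count at `horizon`), and `params` (per-country parameter list).
#' @export
simulate_cohort <- function(n_countries = 170,
                            preset = c("world", "null", "income-groups", "tax-split"),
                            effect = NULL,
                            pre_trend = c(-0.01, 0, 0),
                            noise_sd = 0.02, ar1_rho = 0.5,
                            years = 1994:2020, horizon = 10,
                            include_china = FALSE, seed = NULL,
                            round_counts = TRUE) {
  preset <- match.arg(preset)
  with_seed_(seed, {
    ids <- sprintf("C%03d", seq_len(n_countries))
    rat <- sample_ratification_years(n_countries)
    income <- sample(income_groups(), n_countries,
      replace = TRUE, prob = c(0.30, 0.29, 0.28, 0.13)
    )
    # tax data available for ~95% of countries; ~14% of those high-change
    has_tax <- stats::runif(n_countries) < 0.95
    high_tax <- has_tax & stats::runif(n_countries) < 0.14

    base_effect <- list(level = 0, slope = -0.015, quad = 0)
    if (preset == "null") base_effect <- list(level = 0, slope = 0, quad = 0)
    if (!is.null(effect)) base_effect[names(effect)] <- effect

    slope_of <- function(i) {
      switch(preset,
        "world" = base_effect$slope,
        "null" = base_effect$slope,
        "income-groups" = unname(default_income_effects()[income[i]]),
        "tax-split" = if (high_tax[i]) -0.027 else -0.012
      )
    }
    group_of <- function(i) {
      switch(preset,
        "world" = "world",
        "null" = "world",
        "income-groups" = income[i],
        "tax-split" = if (!has_tax[i]) {
          NA_character_
        } else if (high_tax[i]) "high-tax-change" else "low-tax-change"
      )
    }

    params <- purrr::map(seq_len(n_countries), function(i) {
      sim_country_params(
        country_id = ids[i],
        ratification_year = rat[i],
        baseline_log_smokers = log(2e5) + stats::rnorm(1, 0, 0.8),
        pre_trend = pre_trend,
        level_change = base_effect$level,
        slope_change = slope_of(i),
        quad_change = base_effect$quad,
        noise_sd = noise_sd, ar1_rho = ar1_rho,
        baseline_prevalence = stats::runif(1, 0.08, 0.25),
        pop_growth = stats::runif(1, 0.00, 0.02),
        quit_baseline = stats::runif(1, 0.2, 0.4),
        quit_trend = 0.003,
        quit_drift = if (preset == "null") 0 else 0.002
      )
    })
    if (include_china) {
      params <- c(params, list(sim_country_params(
        country_id = "CHN", ratification_year = 2005,
        baseline_log_smokers = log(3.5e7), pre_trend = pre_trend,
        level_change = 0, slope_change = 0.005, quad_change = 0,
        noise_sd = noise_sd, ar1_rho = ar1_rho,
        baseline_prevalence = 0.11, quit_baseline = 0.12
      )))
      income <- c(income, "upper-middle")
      rat <- c(rat, 2005L)
      has_tax <- c(has_tax, TRUE)
      high_tax <- c(high_tax, FALSE)
      ids <- c(ids, "CHN")
    }

    panel <- dplyr::bind_rows(purrr::map(
      params, simulate_country,
      years = years, round_counts = round_counts
    ))
    meta <- tibble::tibble(
      country_id = ids,
      ratification_year = as.integer(rat),
      income_group = income,
      tax_share_2008 = ifelse(has_tax, round(stats::runif(length(ids), 20, 70), 1), NA_real_),
      tax_change_pp = dplyr::case_when(
        !has_tax ~ NA_real_,
        high_tax ~ round(stats::runif(length(ids), 10, 25), 1),
        TRUE ~ round(stats::runif(length(ids), -5, 9.5), 1)
      ),
      survey_years_count = sample(0:30, length(ids), replace = TRUE)
    )

    truth <- sim_truth(params, group = vapply(seq_along(params), function(i) {
      if (ids[i] == "CHN") "CHN" else group_of(i)
    }, character(1)), horizon = horizon)

    structure(
      list(panel = panel, meta = meta, truth = truth, params = params),
      class = "itsa_sim"
    )
  })
}

#' Ground truth implied by simulation parameters
#'
#' Derives, per group, the true average post-ratification trend change (mean
#' derivative of the break over `I = 0..horizon`, in %/yr), the true
#' cumulative effect at the horizon (in %), and the true averted count at the
#' horizon (projected-minus-actual on the noiseless aggregated curves).
#' Because break parameters are shared within a group, the aggregate closed
#' form and the noiseless-curve computation coincide.
#'
#' @param params List of [sim_country_params()].
#' @param group Character vector of group labels, one per country.
#' @param horizon Evaluation horizon in years.
#' @param pre_window Window anchor used by the generator (default 10).
#' @return A tibble with one row per group.
#' @export
sim_truth <- function(params, group, horizon = 10, pre_window = 10) {
  stopifnot(length(params) == length(group))
  keep <- !is.na(group)
  by_group <- split(params[keep], group[keep])
  rows <- purrr::imap(by_group, function(ps, gname) {
    lev <- unique(vapply(ps, `[[`, numeric(1), "level_change"))
    slo <- unique(vapply(ps, `[[`, numeric(1), "slope_change"))
    qua <- unique(vapply(ps, `[[`, numeric(1), "quad_change"))
    if (length(lev) > 1 || length(slo) > 1 || length(qua) > 1) {
      stop("break parameters differ within group '", gname,
        "'; group-level truth is undefined in closed form",
        call. = FALSE
      )
    }
    ii <- 0:horizon
    delta_h <- lev + slo * horizon + qua * horizon^2
    projected_h <- sum(vapply(ps, function(p) {
      yr <- p$ratification_year + horizon
      exp(sim_mean_curves(p, yr, pre_window)$pre)
    }, numeric(1)))
    tibble::tibble(
      group = gname,
      true_avg_trend_change_pct = 100 * mean(slo + 2 * qua * ii),
      true_cumulative_pct = 100 * delta_h,
      true_projected = projected_h,
      true_averted = projected_h * (1 - exp(delta_h)),
      horizon = as.integer(horizon)
    )
  })
  dplyr::bind_rows(rows)
}
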