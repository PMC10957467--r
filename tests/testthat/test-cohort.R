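sim_two_countries <- function(seed = 42) {
  pa <- sim_country_params("AAA",
    ratification_year = 2005, noise_sd = 0,
    baseline_log_smokers = log(5e4)
  )
  pb <- sim_country_params("BBB",
    ratification_year = 2007, noise_sd = 0,
    baseline_log_smokers = log(2e5), baseline_prevalence = 0.22
  )
  meta <- tibble::tibble(
    country_id = c("AAA", "BBB"), ratification_year = c(2005L, 2007L)
  )
  panel <- dplyr::bind_rows(
    simulate_country(pa, 1995:2015, seed = seed),
    simulate_country(pb, 1997:2017, seed = seed + 1)
  )
  list(panel = panel, meta = meta)
}

test_that("realignment centers each country on its own ratification year", {
  d <- sim_two_countries()
  ev <- realign(d$panel, d$meta)
  a <- ev[ev$country_id == "AAA" & ev$age_band == "10-24", ]
  b <- ev[ev$country_id == "BBB" & ev$age_band == "10-24", ]
  expect_equal(a$calendar_year[a$event_time == 0], 2005)
  expect_equal(b$calendar_year[b$event_time == 0], 2007)
  expect_equal(b$calendar_year[b$event_time == -10], 1997)
  expect_equal(nrow(a), 21)
  expect_equal(sort(unique(a$event_time)), -10:10)
})

test_that("realignment is a pure reindexing: counts inside the window are preserved", {
  d <- sim_two_countries()
  ev <- realign(d$panel, d$meta)
  inside <- dplyr::semi_join(
    d$panel,
    dplyr::mutate(ev, year = .data$calendar_year),
    by = c("country_id", "year", "age_band")
  )
  expect_equal(sum(ev$current_smokers), sum(inside$current_smokers))
  expect_equal(sum(ev$population), sum(inside$population))
})

test_that("incomplete window coverage is an error naming missing years", {
  d <- sim_two_countries()
  short <- d$panel[!(d$panel$country_id == "AAA" & d$panel$year < 1999), ]
  expect_error(realign(short, d$meta), "AAA.*1995.*1996.*1997.*1998")
})

test_that("the alternative-start rule moves early ratifiers to the binding year", {
  p <- sim_country_params("AAA", ratification_year = 2004, noise_sd = 0)
  panel <- simulate_country(p, 1994:2015)
  meta <- tibble::tibble(country_id = "AAA", ratification_year = 2004L)
  ev <- realign(panel, meta, window_config(alt_start_year = 2005))
  expect_equal(ev$calendar_year[ev$event_time == 0 & ev$age_band == "10-24"], 2005)
})

test_that("window_config enforces its bounds", {
  expect_error(window_config(pre_window = 2))
  expect_error(window_config(post_window = 0))
  w <- window_config(13, 10)
  expect_equal(w$pre_window, 13L)
})

test_that("group aggregation sums counts and derives outcomes from the sums", {
  d <- sim_two_countries()
  ev <- realign(d$panel, d$meta)
  g2 <- tibble::tibble(group = "both", country_id = c("AAA", "BBB"))
  gs <- aggregate_group(ev, g2)

  a0 <- ev[ev$country_id == "AAA" & ev$event_time == 0 & ev$age_band == "10-24", ]
  b0 <- ev[ev$country_id == "BBB" & ev$event_time == 0 & ev$age_band == "10-24", ]
  expect_equal(
    gs$smokers_u25[gs$event_time == 0],
    a0$current_smokers + b0$current_smokers
  )
  # ratio of sums, not mean of ratios
  expect_equal(
    gs$log_prevalence,
    log(gs$smokers_u25 / gs$population_u25)
  )
  # merged prevalence lies between member prevalences
  ga <- aggregate_group(ev, tibble::tibble(group = "a", country_id = "AAA"))
  gb <- aggregate_group(ev, tibble::tibble(group = "b", country_id = "BBB"))
  pa <- exp(ga$log_prevalence)
  pb <- exp(gb$log_prevalence)
  pm <- exp(gs$log_prevalence)
  expect_true(all(pm >= pmin(pa, pb) - 1e-12 & pm <= pmax(pa, pb) + 1e-12))
})

test_that("aggregation is invariant to member order and identity on single countries", {
  d <- sim_two_countries()
  ev <- realign(d$panel, d$meta)
  g1 <- tibble::tibble(group = "g", country_id = c("AAA", "BBB"))
  g2 <- tibble::tibble(group = "g", country_id = c("BBB", "AAA"))
  expect_equal(aggregate_group(ev, g1), aggregate_group(ev, g2))

  ga <- aggregate_group(ev, tibble::tibble(group = "solo", country_id = "AAA"))
  a <- ev[ev$country_id == "AAA" & ev$age_band == "10-24", ]
  expect_equal(ga$smokers_u25, a$current_smokers[order(a$event_time)])
})

test_that("aggregation refuses members missing from the event series", {
  d <- sim_two_countries()
  ev <- realign(d$panel, d$meta)
  g <- tibble::tibble(group = "g", country_id = c("AAA", "ZZZ"))
  expect_error(aggregate_group(ev, g), "missing from event series: ZZZ")
})

test_that("quit ratio reproduces worked descriptive values and guards its domain", {
  expect_equal(quit_ratio(79, 231), 0.342, tolerance = 0.002)
  expect_equal(quit_ratio(10, 86), 0.116, tolerance = 0.005)
  expect_equal(quit_ratio(5, 5), 1)
  expect_error(quit_ratio(1, 0), "ever smokers must be > 0")
  expect_error(quit_ratio(6, 5), "exceed")
})
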