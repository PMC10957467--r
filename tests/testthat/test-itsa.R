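test_that("design matrices have the documented shape and coding", {
  s <- toy_series(rnorm(21))
  d1 <- build_design(s, 1)
  expect_equal(nrow(d1), 21)
  expect_equal(d1$T, 1:21)
  # model 1: intercept + T + X + X_I -> 4 coefficients
  f1 <- fit_itsa(s, model_id = 1)
  expect_length(f1$coefficients, 4)
  f5 <- fit_itsa(s, model_id = 5)
  expect_length(f5$coefficients, 7)
  # pre-period coding
  expect_equal(d1$X[d1$event_time == -3], 0)
  expect_equal(d1$I[d1$event_time == -3], 0)
  expect_equal(d1$X[d1$event_time == 0], 1)
  expect_equal(d1$I[d1$event_time == 0], 0)
  expect_equal(d1$I[d1$event_time == 7], 7)
  expect_error(itsa_spec(6), "unknown model_id")
  expect_error(
    build_design(tibble::tibble(event_time = c(-2, 0, 1)), 1),
    "contiguous"
  )
})

test_that("exact linear data are interpolated with zero residuals", {
  y <- 2 + 0.1 * (1:21)
  f <- fit_itsa(toy_series(y), model_id = 1)
  expect_equal(unname(f$coefficients["T"]), 0.1, tolerance = 1e-10)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-10)
})

test_that("OLS coefficients match a normal-equations oracle on random designs", {
  set.seed(11)
  for (m in 1:5) {
    y <- series_from_beta(random_beta(), noise_sd = 0.05, rho = 0.3)
    f <- fit_itsa(toy_series(y), model_id = m)
    X <- fit_X(f)
    expect_equal(unname(f$coefficients), ols_oracle(X, f$y), tolerance = 1e-10)
  }
})

test_that("HAC covariance equals the double-sum Bartlett oracle, incl. the 12-point AR(1) fixture", {
  set.seed(7)
  # 12-point fixture with AR(1) noise, minimal window
  y12 <- 5 - 0.02 * (1:12) +
    as.numeric(arima.sim(list(ar = 0.6), 12)) * 0.03
  f12 <- fit_itsa(toy_series(y12, pre_window = 6, post_window = 5),
    model_id = 1, hac_lags = 3
  )
  expect_equal(
    unname(f12$vcov_hac),
    unname(nw_oracle(fit_X(f12), f12$residuals, 3)),
    tolerance = 1e-10
  )
  # lag 0 reduces to the White heteroskedasticity-only sandwich
  f0 <- fit_itsa(toy_series(y12, pre_window = 6, post_window = 5),
    model_id = 1, hac_lags = 0
  )
  expect_equal(
    unname(f0$vcov_hac),
    unname(nw_oracle(fit_X(f0), f0$residuals, 0)),
    tolerance = 1e-10
  )
})

test_that("coefficients do not depend on the HAC truncation lag", {
  set.seed(3)
  y <- series_from_beta(random_beta(), noise_sd = 0.04, rho = 0.5)
  fits <- lapply(c(0, 1, 2, 5), function(L) fit_itsa(toy_series(y), 3, hac_lags = L))
  for (f in fits[-1]) {
    expect_identical(f$coefficients, fits[[1]]$coefficients)
  }
})

test_that("noiseless polynomial data without a break give zero post coefficients", {
  for (deg in 1:3) {
    beta <- c(10, -0.01, 0, 0, 0, 0, 0)
    if (deg >= 2) beta[3] <- 4e-4
    if (deg >= 3) beta[4] <- -1e-5
    y <- series_from_beta(beta)
    model <- c(1, 2, 4)[deg] # matching pre-degree, post level+slope
    f <- fit_itsa(toy_series(y), model_id = model)
    post <- intersect(names(f$coefficients), c("X", "X_I", "X_I2"))
    expect_lt(max(abs(f$coefficients[post])), 1e-8)
  }
})

test_that("default HAC truncation follows the automatic rule", {
  y <- rnorm(21)
  f <- fit_itsa(toy_series(y), model_id = 1)
  expect_equal(f$hac_lags, 2L) # floor(4*(21/100)^(2/9))
})

test_that("AIC selection picks the minimum and breaks ties toward the smaller model", {
  set.seed(5)
  y <- series_from_beta(random_beta(), noise_sd = 0.03, rho = 0.2)
  fits <- fit_itsa_models(toy_series(y))
  sel <- select_model(fits)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  expect_equal(sel$aic, min(aics))
  # tie rule: duplicate the best fit under a larger id
  tie <- fits[[which.min(aics)]]
  tie$spec$model_id <- 5L
  sel2 <- select_model(list(fits[[which.min(aics)]], tie))
  expect_equal(sel2$spec$model_id, unname(which.min(aics)))
  # single candidate passes through; empty collection errors
  expect_identical(select_model(fits[2])$coefficients, fits[[2]]$coefficients)
  expect_error(select_model(list()), "no fits")
})

test_that("pre-window AIC selection is available and ranks by pre-period fit", {
  set.seed(6)
  y <- series_from_beta(c(10, -0.01, 5e-4, 0, 0, 0, 0), noise_sd = 0.002)
  fits <- fit_itsa_models(toy_series(y))
  sel <- select_model(fits, aic_window = "pre")
  expect_s3_class(sel, "itsa_fit")
  expect_gte(sel$spec$pre_degree, 2)
})

test_that("model selection recovers a quadratic pre-trend in the majority of low-noise draws", {
  set.seed(8)
  picks <- replicate(60, {
    y <- series_from_beta(c(10, -0.015, 6e-4, 0, 0, -0.01, 0), noise_sd = 0.004)
    select_model(fit_itsa_models(toy_series(y)))$spec$model_id
  })
  expect_gt(mean(picks %in% 2:5), 0.8) # pre-degree >= 2
})

test_that("tidy and glance return the documented broom shapes", {
  y <- series_from_beta(random_beta(), noise_sd = 0.02)
  f <- fit_itsa(toy_series(y), model_id = 3)
  td <- tidy(f, conf.int = TRUE)
  expect_named(
    td,
    c("term", "estimate", "std.error", "statistic", "p.value", "conf.low", "conf.high")
  )
  expect_equal(nrow(td), 6)
  gl <- glance(f)
  expect_equal(gl$model_id, 3)
  expect_equal(gl$n_obs, 21)
  expect_true(is.finite(gl$aic))
})
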