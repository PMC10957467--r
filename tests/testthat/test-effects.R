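fit_from_beta <- function(beta, model_id, noise_sd = 0, rho = 0) {
  y <- series_from_beta(beta, noise_sd = noise_sd, rho = rho)
  fit_itsa(toy_series(y), model_id = model_id)
}

test_that("average pre-ratification trend matches the closed forms", {
  # constant slope: beta1 = -0.005 -> -0.5 %/yr
  f <- fit_from_beta(c(10, -0.005, 0, 0, 0, 0, 0), 1)
  expect_equal(avg_pre_trend(f)$estimate, -0.5, tolerance = 1e-8)
  # quadratic: 100*(0.01 - 0.002*mean(1:10)) = -0.1 %/yr
  f2 <- fit_from_beta(c(10, 0.01, -0.001, 0, 0, 0, 0), 2)
  expect_equal(avg_pre_trend(f2)$estimate, -0.1, tolerance = 1e-8)
})

test_that("average trend change matches the closed forms", {
  f <- fit_from_beta(c(10, 0, 0, 0, 0, -0.008, 0), 1)
  expect_equal(avg_trend_change(f)$estimate, -0.8, tolerance = 1e-8)
  f0 <- fit_from_beta(c(10, -0.01, 0, 0, 0.02, 0, 0), 1)
  expect_equal(avg_trend_change(f0)$estimate, 0, tolerance = 1e-8)
})

test_that("cumulative effect matches the direct formula", {
  f0 <- fit_from_beta(c(10, -0.01, 0, 0, 0, 0, 0), 3)
  expect_equal(cumulative_effect(f0, 10)$estimate, 0, tolerance = 1e-8)
  f <- fit_from_beta(c(10, 0, 0, 0, 0.01, -0.02, 0.001), 3)
  expect_equal(cumulative_effect(f, 10)$estimate, -9.0, tolerance = 1e-8)
  expect_error(cumulative_effect(f, 11), "horizon exceeds")
})

test_that("margins equal central-difference / direct-evaluation oracles on all five specs", {
  set.seed(21)
  for (m in 1:5) {
    f <- fit_itsa(toy_series(series_from_beta(random_beta(), noise_sd = 0.01)),
      model_id = m
    )
    curve <- fit_curve(f)
    t0 <- f$design$T[f$design$event_time == 0]

    pre_oracle <- 100 * mean(num_deriv(curve, f$design$T[f$design$event_time < 0]))
    expect_equal(avg_pre_trend(f)$estimate, pre_oracle, tolerance = 1e-6)

    # derivative w.r.t. I on the post segment: finite difference of the
    # break component b4 + b5*I + b6*I^2
    brk <- function(ii) {
      cf <- f$coefficients
      get0 <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
      get0("X") + get0("X_I") * ii + get0("X_I2") * ii^2
    }
    h <- 1e-5
    tc_oracle <- 100 * mean((brk(0:10 + h) - brk(0:10 - h)) / (2 * h))
    expect_equal(avg_trend_change(f, horizon = 10)$estimate, tc_oracle,
      tolerance = 1e-6
    )
    expect_equal(cumulative_effect(f, 10)$estimate, 100 * brk(10),
      tolerance = 1e-8
    )
  }
})

test_that("delta-method CIs agree with a Monte-Carlo draw from the HAC covariance", {
  set.seed(31)
  f <- fit_from_beta(c(12, -0.02, 5e-4, 0, 0.01, -0.01, 0), 3,
    noise_sd = 0.02, rho = 0.5
  )
  eff <- cumulative_effect(f, 10)
  # draw coefficient vectors from N(beta, V_hac) and evaluate the effect
  b <- f$coefficients
  V <- f$vcov_hac
  L <- chol(V)
  n <- 1e5
  draws <- matrix(rnorm(n * length(b)), n) %*% L
  draws <- sweep(draws, 2, b, "+")
  colnames(draws) <- names(b)
  vals <- 100 * (draws[, "X"] + 10 * draws[, "X_I"] + 100 * draws[, "X_I2"])
  qs <- quantile(vals, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(eff$conf.low - qs[1]), 0.1)
  expect_lt(abs(eff$conf.high - qs[2]), 0.1)
  expect_true(eff$conf.low < eff$estimate & eff$estimate < eff$conf.high)
})

test_that("for post-linear models the cumulative effect grows linearly in the horizon", {
  set.seed(41)
  f <- fit_from_beta(random_beta() * c(1, 1, 1, 1, 1, 1, 0), 4,
    noise_sd = 0.01
  )
  tc <- avg_trend_change(f, horizon = 10)$estimate
  c10 <- cumulative_effect(f, 10)$estimate
  c0 <- cumulative_effect(f, 0)$estimate
  expect_equal(c10 - c0, 10 * tc, tolerance = 1e-8)
})

test_that("effects are invariant to the time-trend origin", {
  set.seed(51)
  y <- series_from_beta(random_beta(), noise_sd = 0.02)
  f <- fit_itsa(toy_series(y), model_id = 5)
  # refit with T shifted by +7: rebuild the design by hand, refit, rewrap
  shift <- 7
  d <- f$design
  d$T <- d$T + shift
  d$T2 <- d$T^2
  d$T3 <- d$T^3
  dat <- data.frame(
    .y = f$y, T = d$T, T2 = d$T2, T3 = d$T3,
    X = d$X, X_I = d$X_I, X_I2 = d$X_I2
  )
  lmfit <- lm(.y ~ T + T2 + T3 + X + X_I + X_I2, data = dat)
  f2 <- f
  f2$coefficients <- coef(lmfit)
  f2$vcov_hac <- sandwich::NeweyWest(lmfit, lag = f$hac_lags, prewhite = FALSE, adjust = FALSE)
  f2$residuals <- unname(resid(lmfit))
  f2$fitted <- unname(fitted(lmfit))
  f2$design <- d
  for (fun in list(avg_pre_trend, avg_trend_change, cumulative_effect)) {
    expect_equal(fun(f2)$estimate, fun(f)$estimate, tolerance = 1e-6)
  }
})

test_that("the exact-percent option applies the log-to-relative transform", {
  f <- fit_from_beta(c(10, 0, 0, 0, -0.10, -0.01, 0), 1)
  lp <- cumulative_effect(f, 10)
  ex <- cumulative_effect(f, 10, percent = "exact")
  expect_equal(ex$estimate, (exp(lp$estimate / 100) - 1) * 100, tolerance = 1e-8)
})

test_that("itsa_effects stacks the three quantities for one fit", {
  f <- fit_from_beta(random_beta(), 2, noise_sd = 0.01)
  tab <- itsa_effects(f, horizon = 10)
  expect_equal(tab$quantity, c("avg_pre_trend", "avg_trend_change", "cumulative_effect"))
  expect_true(all(tab$conf.low <= tab$estimate & tab$estimate <= tab$conf.high))
})
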