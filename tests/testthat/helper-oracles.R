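# Independent oracles, coded from first principles and never calling the
# package's fitting internals (or sandwich).

# Newey-West HAC covariance: textbook double-sum with Bartlett weights
nw_oracle <- function(X, e, lag) {
  X <- as.matrix(X)
  n <- nrow(X)
  XtXi <- solve(crossprod(X))
  S <- matrix(0, ncol(X), ncol(X))
  for (t in seq_len(n)) S <- S + e[t]^2 * tcrossprod(X[t, ])
  if (lag > 0) {
    for (j in seq_len(lag)) {
      w <- 1 - j / (lag + 1)
      for (t in (j + 1):n) {
        A <- tcrossprod(X[t, ], X[t - j, ])
        S <- S + w * e[t] * e[t - j] * (A + t(A))
      }
    }
  }
  XtXi %*% S %*% XtXi
}

# OLS via the normal equations
ols_oracle <- function(X, y) unname(drop(solve(crossprod(X), crossprod(X, y))))

# design matrix (with intercept) of a fit, in the fit's own column order
fit_X <- function(fit) {
  terms <- names(fit$coefficients)
  cols <- lapply(terms, function(tm) {
    if (tm == "(Intercept)") rep(1, nrow(fit$design)) else fit$design[[tm]]
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

# fitted segmented curve evaluated on a real-valued time axis, from the
# coefficient vector alone (for central-difference derivative oracles)
fit_curve <- function(fit) {
  b <- numeric(7)
  names(b) <- c("(Intercept)", "T", "T2", "T3", "X", "X_I", "X_I2")
  b[names(fit$coefficients)] <- fit$coefficients
  t0 <- fit$design$T[fit$design$event_time == 0]
  function(tt) {
    ii <- pmax(tt - t0, 0)
    xx <- as.numeric(tt >= t0)
    b["(Intercept)"] + b["T"] * tt + b["T2"] * tt^2 + b["T3"] * tt^3 +
      xx * (b["X"] + b["X_I"] * ii + b["X_I2"] * ii^2)
  }
}

# central-difference derivative
num_deriv <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# a one-group series tibble from an outcome vector on a standard window
toy_series <- function(y, pre_window = 10, post_window = 10,
                       outcome = "log_smokers", group = "g") {
  stopifnot(length(y) == pre_window + post_window + 1)
  out <- tibble::tibble(
    group = group,
    event_time = seq(-pre_window, post_window)
  )
  out[[outcome]] <- y
  out
}

# outcome vector generated from known beta0..beta6 on a standard window
series_from_beta <- function(beta, pre_window = 10, post_window = 10,
                             noise_sd = 0, rho = 0) {
  t_ev <- seq(-pre_window, post_window)
  tt <- seq_along(t_ev)
  ii <- pmax(t_ev, 0)
  xx <- as.numeric(t_ev >= 0)
  mu <- beta[1] + beta[2] * tt + beta[3] * tt^2 + beta[4] * tt^3 +
    xx * (beta[5] + beta[6] * ii + beta[7] * ii^2)
  if (noise_sd > 0) {
    e <- if (rho == 0) {
      stats::rnorm(length(mu), sd = noise_sd)
    } else {
      as.numeric(stats::arima.sim(list(ar = rho), length(mu))) *
        noise_sd * sqrt(1 - rho^2)
    }
    mu <- mu + e
  }
  mu
}

# random model coefficients sized so every term matters on a 21-point window
random_beta <- function() {
  c(
    stats::runif(1, 10, 15), # intercept
    stats::runif(1, -0.05, 0.05), # T
    stats::runif(1, -2e-3, 2e-3), # T^2
    stats::runif(1, -5e-5, 5e-5), # T^3
    stats::runif(1, -0.05, 0.05), # X
    stats::runif(1, -0.02, 0.02), # X*I
    stats::runif(1, -2e-3, 2e-3) # X*I^2
  )
}

# a tiny valid 3-row panel for IO tests
tiny_panel <- function() {
  tibble::tibble(
    country_id = c("AAA", "AAA", "BBB"),
    year = c(2000L, 2000L, 2000L),
    age_band = c("10-24", "45-59", "10-24"),
    current_smokers = c(100, 50, 200),
    population = c(1000, 400, 1500),
    former_smokers = c(NA, 30, NA),
    ever_smokers = c(NA, 80, NA)
  )
}
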