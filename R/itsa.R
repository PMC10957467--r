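#' Segmented trend model specifications
#'
#' The five interrupted time series specifications differ only in the
#' polynomial degree of the secular (pre-ratification) trend and of the
#' post-ratification trend change:
#'
#' | model | pre trend | post trend terms |
#' |-------|-----------|------------------|
#' | 1 | linear    | level + slope |
#' | 2 | quadratic | level + slope |
#' | 3 | quadratic | level + slope + quadratic |
#' | 4 | cubic     | level + slope |
#' | 5 | cubic     | level + slope + quadratic |
#'
#' All include an intercept, time trend terms `T, T^2, T^3` up to the pre
#' degree, a post-period indicator `X` (the level change), and interaction
#' terms `X*I, X*I^2` up to the post degree, where `I` is years since
#' ratification (0 before and at ratification).
#'
#' @param model_id Integer 1-5.
#' @return A list of class `itsa_spec` with `model_id`, `pre_degree`,
#'   `post_degree`.
#' @export
itsa_spec <- function(model_id) {
  degrees <- list(
    `1` = c(1L, 1L), `2` = c(2L, 1L), `3` = c(2L, 2L),
    `4` = c(3L, 1L), `5` = c(3L, 2L)
  )
  key <- as.character(model_id)
  if (length(model_id) != 1 || is.na(model_id) || !key %in% names(degrees)) {
    stop("unknown model_id (must be 1-5): ", model_id, call. = FALSE)
  }
  d <- degrees[[key]]
  structure(
    list(model_id = as.integer(model_id), pre_degree = d[1], post_degree = d[2]),
    class = "itsa_spec"
  )
}

# canonical term names in beta0..beta6 order
itsa_terms <- function() c("(Intercept)", "T", "T2", "T3", "X", "X_I", "X_I2")

spec_terms <- function(spec) {
  pre <- c("T", "T2", "T3")[seq_len(spec$pre_degree)]
  post <- c("X_I", "X_I2")[seq_len(spec$post_degree)]
  c("(Intercept)", pre, "X", post)
}

#' Build the regressor matrix for a segmented trend model
#'
#' Encodes the event-time series as the ITSA regressors: `T` runs 1..n in
#' window order (origin cosmetic: trend and cumulative effects are invariant
#' to it), `X = 1` from the ratification year on (event time >= 0), and
#' `I = max(event_time, 0)` so the post slope accumulates from 0 at
#' ratification.
#'
#' @param series A single group's rows of a group-series tibble (must have
#'   `event_time`), or any tibble with an `event_time` column.
#' @param spec An [itsa_spec()] or a model id 1-5.
#' @return A tibble with `event_time`, `T`, `X`, `I` and one column per model
#'   regressor beyond the intercept; the spec is attached as attribute
#'   `"spec"`.
#' @export
build_design <- function(series, spec) {
  if (!inherits(spec, "itsa_spec")) spec <- itsa_spec(spec)
  t_ev <- sort(unique(series$event_time))
  if (length(t_ev) != length(series$event_time)) {
    stop("series must contain one row per event_time (a single group)", call. = FALSE)
  }
  if (!all(diff(t_ev) == 1)) {
    stop("event_time must be contiguous with no gaps", call. = FALSE)
  }
  tt <- seq_along(t_ev)
  xx <- as.integer(t_ev >= 0)
  ii <- pmax(t_ev, 0)
  d <- tibble::tibble(
    event_time = t_ev, T = tt, X = xx, I = ii,
    T2 = tt^2, T3 = tt^3, X_I = xx * ii, X_I2 = xx * ii^2
  )
  keep <- c("event_time", "T", "X", "I", setdiff(spec_terms(spec), c("(Intercept)", "T", "X")))
  d <- d[, unique(keep)]
  attr(d, "spec") <- spec
  d
}

default_hac_lags <- function(n) as.integer(floor(4 * (n / 100)^(2 / 9)))

#' Fit one segmented trend model with Newey-West errors
#'
#' Ordinary least squares on the model's regressors, with a
#' heteroskedasticity-and-autocorrelation-consistent (HAC, Newey-West with
#' Bartlett kernel) coefficient covariance. The point estimates are plain
#' OLS; only the covariance depends on `hac_lags`. The AIC reported is
#' `n*log(RSS/n) + 2k` (Gaussian likelihood up to an additive constant,
#' consistent across the five models so comparisons are internal).
#'
#' @param series A single group's group-series rows ([aggregate_group()]).
#' @param outcome Outcome column name, usually one of `"log_smokers"`,
#'   `"log_prevalence"`, `"log_quit_ratio"` (or `"log_former"` for the
#'   quitters counterfactual).
#' @param model_id Model id 1-5 or an [itsa_spec()].
#' @param hac_lags Bartlett truncation lag; default
#'   `floor(4*(n/100)^(2/9))` (2 for the standard 21-point window). 0 gives
#'   the heteroskedasticity-only (White) sandwich.
#' @return An object of class `itsa_fit`: coefficients, HAC covariance,
#'   residuals, AIC, the spec, and the data fitted.
#' @export
fit_itsa <- function(series, outcome = "log_smokers", model_id = 1,
                     hac_lags = NULL) {
  design <- build_design(series, model_id)
  spec <- attr(design, "spec")
  y <- series[[outcome]][order(series$event_time)]
  if (is.null(y)) stop("outcome column not found: ", outcome, call. = FALSE)
  if (!all(is.finite(y))) stop("outcome contains non-finite values", call. = FALSE)
  terms <- setdiff(spec_terms(spec), "(Intercept)")
  n <- length(y)
  if (n < length(terms) + 2) {
    stop("too few observations for model ", spec$model_id, call. = FALSE)
  }
  dat <- as.data.frame(design[, terms])
  dat$.y <- y
  fml <- stats::reformulate(sprintf("`%s`", terms), response = ".y")
  lmfit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(lmfit)))) {
    stop("rank-deficient design for model ", spec$model_id, call. = FALSE)
  }
  if (is.null(hac_lags)) hac_lags <- default_hac_lags(n)
  # bread.lm warns about "essentially perfect fit" on noiseless fixtures;
  # the covariance itself is still well-defined
  vc <- withCallingHandlers(
    sandwich::NeweyWest(lmfit, lag = hac_lags, prewhite = FALSE, adjust = FALSE),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- stats::coef(lmfit)
  names(coefs) <- sub("^`|`$", "", names(coefs))
  dimnames(vc) <- list(names(coefs), names(coefs))
  rss <- sum(stats::resid(lmfit)^2)
  k <- length(coefs)
  structure(
    list(
      spec = spec,
      outcome = outcome,
      group = if (!is.null(series$group)) series$group[1] else NA_character_,
      coefficients = coefs,
      vcov_hac = vc,
      residuals = unname(stats::resid(lmfit)),
      fitted = unname(stats::fitted(lmfit)),
      aic = n * log(rss / n) + 2 * k,
      n_obs = n,
      hac_lags = hac_lags,
      design = design,
      y = y,
      lm = lmfit
    ),
    class = "itsa_fit"
  )
}

# coefficients / HAC covariance embedded into the full beta0..beta6 frame,
# zeros for terms absent from the spec
full_beta <- function(fit) {
  b <- stats::setNames(numeric(7), itsa_terms())
  b[names(fit$coefficients)] <- fit$coefficients
  b
}

full_vcov <- function(fit) {
  v <- matrix(0, 7, 7, dimnames = list(itsa_terms(), itsa_terms()))
  v[names(fit$coefficients), names(fit$coefficients)] <- fit$vcov_hac
  v
}

pre_window_of <- function(fit) sum(fit$design$event_time < 0)
post_window_of <- function(fit) sum(fit$design$event_time > 0)

#' Fit all candidate segmented trend models
#'
#' @inheritParams fit_itsa
#' @param model_ids Models to fit (default all five).
#' @return A list of `itsa_fit` objects named by model id.
#' @export
fit_itsa_models <- function(series, outcome = "log_smokers", model_ids = 1:5,
                            hac_lags = NULL) {
  fits <- lapply(model_ids, function(m) fit_itsa(series, outcome, m, hac_lags))
  stats::setNames(fits, paste0("model", model_ids))
}

#' Select the best model by AIC
#'
#' Returns the candidate with minimal AIC; ties go to the smaller model id
#' (fewer parameters, by construction of the id ordering). `aic_window =
#' "pre"` recomputes each candidate's AIC on the pre-ratification rows only
#' (residuals of the full fit restricted to the pre window), for selection
#' keyed to the quality of the before-ratification fit.
#'
#' @param fits A list of `itsa_fit` objects on the same outcome series.
#' @param aic_window `"full"` (default) or `"pre"`.
#' @return The selected `itsa_fit`, with a `selection` element recording the
#'   compared AICs.
#' @export
select_model <- function(fits, aic_window = c("full", "pre")) {
  aic_window <- match.arg(aic_window)
  if (length(fits) == 0) stop("no fits to select from", call. = FALSE)
  aics <- vapply(fits, function(f) {
    if (aic_window == "full") {
      f$aic
    } else {
      pre <- f$design$event_time < 0
      np <- sum(pre)
      np * log(sum(f$residuals[pre]^2) / np) + 2 * length(f$coefficients)
    }
  }, numeric(1))
  ids <- vapply(fits, function(f) f$spec$model_id, integer(1))
  best <- order(aics, ids)[1]
  sel <- fits[[best]]
  sel$selection <- tibble::tibble(model_id = ids, aic = aics, selected = seq_along(fits) == best)
  sel
}

#' @export
print.itsa_fit <- function(x, ...) {
  cat(sprintf(
    "Segmented trend fit (model %d: pre degree %d, post degree %d)\n",
    x$spec$model_id, x$spec$pre_degree, x$spec$post_degree
  ))
  cat(sprintf(
    "  outcome: %s   group: %s   n = %d   HAC lags = %d   AIC = %.3f\n",
    x$outcome, x$group, x$n_obs, x$hac_lags, x$aic
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a segmented trend fit
#'
#' @param x An `itsa_fit`.
#' @param conf.int,conf.level Add normal-theory HAC confidence intervals.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error` (HAC), `statistic`,
#'   `p.value`, and optionally `conf.low`/`conf.high`.
#' @export
tidy.itsa_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov_hac))
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * stats::pnorm(-abs(unname(x$coefficients / se)))
  )
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' Glance at a segmented trend fit
#'
#' @param x An `itsa_fit`.
#' @param ... Unused.
#' @return One-row tibble: model id, degrees, AIC, sigma, r.squared, n,
#'   HAC lags.
#' @export
glance.itsa_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$spec$model_id,
    pre_degree = x$spec$pre_degree,
    post_degree = x$spec$post_degree,
    aic = x$aic,
    sigma = sqrt(sum(x$residuals^2) / stats::df.residual(x$lm)),
    r.squared = 1 - sum(x$residuals^2) / sum((x$y - mean(x$y))^2),
    n_obs = x$n_obs,
    hac_lags = x$hac_lags
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
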