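#' Bootstrap configuration
#'
#' Countries are the resampling unit: once series are aligned in event time,
#' the country is the only exchangeable unit, and temporal dependence within
#' a country is handled by the HAC covariance inside each fit, not by the
#' bootstrap.
#'
#' @param n_replications Number of bootstrap replications (default 100).
#' @param ci_level Confidence level for percentile intervals (default 0.95).
#' @param seed Optional integer seed; the same seed gives identical
#'   intervals.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replications = 100, ci_level = 0.95, seed = NULL) {
  stopifnot(n_replications >= 2, ci_level > 0, ci_level < 1)
  structure(
    list(
      n_replications = as.integer(n_replications),
      ci_level = ci_level, seed = seed
    ),
    class = "bootstrap_config"
  )
}

# run code under a seed without disturbing the caller's RNG stream
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Bootstrap a pipeline statistic by resampling countries
#'
#' For each replication, resamples each group's member countries with
#' replacement (group sizes preserved), re-aggregates the event-aligned
#' series with multiplicity, and recomputes the statistic. Percentile
#' intervals at `ci_level`. A statistic may fail on awkward resamples
#' (e.g. degenerate fits); failures are tolerated up to 20% of replications
#' per group, beyond which an error reports the failure log.
#'
#' @param panel Validated panel tibble.
#' @param meta Country metadata (ratification years).
#' @param grouping Membership tibble from [build_grouping()].
#' @param window A [window_config()].
#' @param statistic Function of one group's group-series tibble returning a
#'   named numeric vector. See [stat_cumulative_effect()],
#'   [stat_quit_ratio()] for ready-made ones.
#' @param config A [bootstrap_config()].
#' @return A tibble with one row per (group, statistic): `estimate` (full
#'   data), `conf.low`, `conf.high`, `n_replications`, `n_failed`.
#'   Replicate draws are attached as attribute `"replicates"`.
#' @export
bootstrap_pipeline <- function(panel, meta, grouping, window = window_config(),
                               statistic, config = bootstrap_config()) {
  events <- realign(
    panel, dplyr::semi_join(meta, grouping, by = "country_id"), window
  )
  groups <- split(grouping$country_id, grouping$group)

  # precompute country x event-time count matrices once; a resample is then
  # four row-subset column sums instead of a re-join
  t_ev <- sort(unique(events$event_time))
  count_matrix <- function(col, band) {
    sub <- events[events$age_band == band, ]
    m <- stats::xtabs(stats::reformulate("country_id + event_time", col), data = sub)
    matrix(m, nrow = nrow(m), dimnames = dimnames(m))
  }
  S <- count_matrix("current_smokers", age_bands()[1])
  P <- count_matrix("population", age_bands()[1])
  FF <- count_matrix("former_smokers", age_bands()[2])
  EE <- count_matrix("ever_smokers", age_bands()[2])

  eval_group <- function(members, gname) {
    idx <- match(members, rownames(S))
    if (anyNA(idx)) {
      stop("group member(s) missing from event series", call. = FALSE)
    }
    sums <- function(m) unname(colSums(m[idx, , drop = FALSE]))
    gs <- tibble::tibble(
      group = gname, event_time = t_ev,
      smokers_u25 = sums(S), population_u25 = sums(P),
      former_45_59 = sums(FF), ever_45_59 = sums(EE)
    )
    if (any(gs$smokers_u25 <= 0 | gs$population_u25 <= 0 |
      gs$former_45_59 <= 0 | gs$ever_45_59 <= 0)) {
      stop("zero aggregate count in resample; log outcomes undefined", call. = FALSE)
    }
    gs$log_smokers <- log(gs$smokers_u25)
    gs$log_prevalence <- log(gs$smokers_u25 / gs$population_u25)
    gs$log_quit_ratio <- log(gs$former_45_59 / gs$ever_45_59)
    gs$log_former <- log(gs$former_45_59)
    statistic(gs)
  }
  point <- purrr::imap(groups, eval_group)

  reps <- with_seed_(config$seed, {
    purrr::map(seq_len(config$n_replications), function(r) {
      purrr::imap(groups, function(members, gname) {
        draw <- sample(members, length(members), replace = TRUE)
        tryCatch(eval_group(draw, gname), error = function(e) e)
      })
    })
  })

  alpha <- (1 - config$ci_level) / 2
  out <- purrr::imap(groups, function(members, gname) {
    vals <- purrr::map(reps, gname)
    failed <- vapply(vals, inherits, logical(1), what = "error")
    if (mean(failed) > 0.2) {
      msgs <- unique(vapply(vals[failed], conditionMessage, character(1)))
      stop(
        sprintf(
          "bootstrap statistic failed on %d/%d replicates for group '%s': %s",
          sum(failed), length(vals), gname, paste(msgs, collapse = "; ")
        ),
        call. = FALSE
      )
    }
    mat <- do.call(rbind, vals[!failed])
    est <- point[[gname]]
    tibble::tibble(
      group = gname,
      statistic = names(est),
      estimate = unname(est),
      conf.low = unname(apply(mat, 2, stats::quantile, probs = alpha, names = FALSE)),
      conf.high = unname(apply(mat, 2, stats::quantile, probs = 1 - alpha, names = FALSE)),
      n_replications = as.integer(config$n_replications),
      n_failed = as.integer(sum(failed))
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "replicates") <- reps
  res
}

#' Ready-made bootstrap statistics
#'
#' Factories returning statistic functions for [bootstrap_pipeline()].
#' `stat_quit_ratio()` reports the quit ratio at an event time (default the
#' ratification year). `stat_group_count()` reports a summed count column at
#' an event time. `stat_cumulative_effect()` runs the full model stage —
#' fit the candidate models, select by AIC, compute the cumulative effect —
#' and reports its point estimate in percent.
#'
#' @param event_time Event time at which to evaluate (default 0).
#' @param column Count column for `stat_group_count`.
#' @param outcome,horizon,model_ids,hac_lags Passed to the model stage.
#' @return A function of a group-series tibble returning a named numeric.
#' @export
stat_quit_ratio <- function(event_time = 0) {
  force(event_time)
  function(gs) {
    row <- gs[gs$event_time == event_time, ]
    c(quit_ratio = quit_ratio(row$former_45_59, row$ever_45_59))
  }
}

#' @rdname stat_quit_ratio
#' @export
stat_group_count <- function(column = "smokers_u25", event_time = 0) {
  force(column)
  force(event_time)
  function(gs) {
    val <- gs[[column]][gs$event_time == event_time]
    stats::setNames(val, column)
  }
}

#' @rdname stat_quit_ratio
#' @export
stat_cumulative_effect <- function(outcome = "log_smokers", horizon = 10,
                                   model_ids = 1:5, hac_lags = NULL) {
  engine <- NULL
  function(gs) {
    if (is.null(engine)) engine <<- cumeffect_engine(gs$event_time, model_ids, horizon)
    y <- gs[[outcome]][order(gs$event_time)]
    c(cumulative_effect_pct = engine(y))
  }
}

# point-estimate engine for the bootstrap: OLS by QR (designs factorized
# once per window shape), AIC = n*log(RSS/n) + 2k, minimum-AIC selection with
# ties to the smaller model id, then the cumulative effect at the horizon.
# Identical by construction to select_model + cumulative_effect (tested);
# only the covariance step is skipped, which percentile intervals never use.
cumeffect_engine <- function(event_time, model_ids = 1:5, horizon = 10) {
  t_ev <- sort(event_time)
  prepared <- lapply(model_ids, function(m) {
    d <- build_design(tibble::tibble(event_time = t_ev), m)
    terms <- setdiff(spec_terms(attr(d, "spec")), "(Intercept)")
    X <- cbind(`(Intercept)` = 1, as.matrix(d[, terms]))
    grad <- stats::setNames(numeric(ncol(X)), colnames(X))
    grad["X"] <- 1
    if ("X_I" %in% colnames(X)) grad["X_I"] <- horizon
    if ("X_I2" %in% colnames(X)) grad["X_I2"] <- horizon^2
    list(qr = qr(X), k = ncol(X), grad = grad)
  })
  n <- length(t_ev)
  function(y) {
    best <- NULL
    best_aic <- Inf
    for (p in prepared) {
      res <- qr.resid(p$qr, y)
      aic <- n * log(sum(res^2) / n) + 2 * p$k
      if (aic < best_aic) {
        best_aic <- aic
        best <- p
      }
    }
    cf <- qr.coef(best$qr, y)
    100 * sum(best$grad * cf)
  }
}
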