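---
title: "Segmented trend models for event-aligned smoking series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented trend models for event-aligned smoking series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fctcitsa)
```

## The model and its assumptions

The package estimates the effect of a country-level intervention — treaty
ratification — on smoking outcomes using interrupted time series analysis
on event-aligned, group-aggregated series. The units of analysis are
country *groups* (the world, four World Bank income classes, high vs low
tobacco-tax-change countries, or single countries), not individual
countries: counts are summed across members at each event time and outcomes
derived from the sums. Three log outcomes are modelled: the log number of
current smokers aged 10–24, the log smoking prevalence at those ages
(summed smokers over summed population), and the log quit ratio at ages
45–59 (summed former over summed ever smokers). Logs turn the marked skew
in country sizes into an additive scale on which coefficients read as
relative (percentage) changes.

Each group series over a window of `pre_window` years before and
`post_window` years after ratification (defaults 10 and 10, so 21 points)
is fitted with five nested segmented polynomial specifications,

$$Y_t = \beta_0 + \beta_1 T_t + \beta_2 T_t^2 + \beta_3 T_t^3
      + \beta_4 X_t + \beta_5 X_t I_t + \beta_6 X_t I_t^2 + \epsilon_t,$$

where each model keeps the pre-trend terms up to its pre degree (1, 2 or 3)
and the post terms up to its post degree (1 or 2): model 1 is linear/linear,
2 quadratic/linear, 3 quadratic/quadratic, 4 cubic/linear, 5
cubic/quadratic. `T` runs 1..21 over the window, `X` switches on at event
time 0, and `I = max(event time, 0)` counts years since ratification.
Estimation is ordinary least squares; inference uses the Newey–West
(Bartlett-kernel) HAC covariance, so serial correlation and
heteroskedasticity in $\epsilon_t$ affect standard errors but not point
estimates. The key identifying assumption is the usual one for interrupted
time series: absent the intervention, the pre-ratification trend (as
captured by the selected polynomial) would have continued.

Because countries ratified in different calendar years (2004–2010 in the
data this design targets), each country's series is first re-indexed to
event time $t = \mathrm{year} - \mathrm{year{:}ratified}$, and groups are
aggregated *in event time* with fixed membership — every member must cover
the full window, and no interpolation is attempted. The ratification year
itself belongs to the post period ($X = 1$, $I = 0$ at $t = 0$). The source
data do not dictate this choice; it is forced here by the convention that
the 10-year cumulative effect is evaluated at $I = 10$ with ten post years
available, which requires $I$ to start at 0 in the ratification year. The
post-period averaging grid for the trend-change margin follows the same
convention ($I = 0..h$) and is configurable (`grid_from = 1`).

## Derived quantities

From the AIC-selected fit the package reports, in percent (100 × log
points; an `"exact"` option applies $(e^\delta - 1) \times 100$):

- the average pre-ratification trend, $\overline{\beta_1 + 2\beta_2 T + 3\beta_3 T^2}$
  over pre-period $T$ values, in %/yr;
- the average post-ratification change in trend, $\overline{\beta_5 + 2\beta_6 I}$
  over $I = 0..h$, in %/yr;
- the cumulative effect at horizon $h$ (default 10),
  $100(\beta_4 + \beta_5 h + \beta_6 h^2)$ — the log-scale gap at $I = h$
  between the fitted post trajectory and the continued pre-trend.

Confidence intervals for these linear functionals use the delta method on
the HAC covariance with normal critical values at 95%.

The counterfactual module exponentiates the pre-trend part
($\beta_0 + \beta_1 T + \beta_2 T^2 + \beta_3 T^3$) over the post window to
get projected counts, and reports averted people as projected minus actual.
Two modes are offered because "fewer smokers over the decade" is ambiguous:
the default `at_horizon` stock difference at year 10 (which is the mode
consistent with pairing an averted percentage with the cumulative effect at
the same horizon: with fitted actuals, `averted_pct` equals
$-(e^\delta - 1) \times 100$ of the log cumulative effect exactly), and a
`cumulative_person_years` mode summing the yearly gaps over event times
1..10. The additional-quitters question reuses the identical machinery on
the former-smoker count series (`log_former`). Scenario reassignment
applies one group's relative decline to another group's projected counts
(e.g. "had every country matched the high-tax-change decline").

## Model selection

Candidates are compared by $AIC = n\log(RSS/n) + 2k$, which orders models
identically to the Gaussian-likelihood AIC and keeps comparisons internal
to a fixed series. Ties break toward the smaller model id (fewer
parameters). Selection can be keyed to the full window (default) or to the
pre-ratification rows only (`aic_window = "pre"`), since "best fit before
ratification" admits both readings; both are exposed rather than guessing.

Two small-sample behaviours of this procedure matter and are documented
rather than hidden:

1. **HAC intervals are anti-conservative at n = 21.** With the automatic
   Bartlett truncation $\lfloor 4(n/100)^{2/9}\rfloor = 2$ and AR(1)
   correlation around 0.5, the HAC variance estimate is biased downward;
   in simulation the nominal 95% delta-method interval of the *true* model
   covers at roughly 60–65%, and of the *selected* model far less, because
   it conditions on the selection.
2. **Cubic extrapolation is fragile.** On smooth 21-point series the
   seven-parameter model 5 often wins the AIC, and its cubic pre-trend can
   extrapolate steeply over the post decade, occasionally producing
   sign-flipped cumulative effects on individual draws. The estimator
   remains approximately unbiased across replications, but its dispersion
   is dominated by which model gets selected.

Both are properties of the estimation strategy itself (five polynomial
candidates, AIC, 21 observations), not of this implementation. The
practical consequence is that pipeline-level uncertainty should come from
the country bootstrap, which re-runs aggregation, fitting and selection on
every resample and therefore propagates selection variability; in
simulation its percentile intervals cover a known effect at ~96%. The
delta-method intervals remain available and are the right tool for
within-model coefficient inference.

## Bootstrap

The resampling unit is the country — after event alignment it is the only
exchangeable unit; serial dependence within a country stays inside each
fit's HAC covariance, so no block bootstrap over time is used. Members are
resampled with replacement within each group (group sizes preserved),
counts re-aggregated with multiplicity, and the statistic recomputed;
intervals are percentile intervals, by default from 100 replications
(matching the descriptive-table convention this design follows;
configurable upward for smoother tails). A statistic is allowed to fail on
up to 20% of resamples before the whole bootstrap aborts with a failure
log. For the model-stage statistic the bootstrap uses a QR fast path that
reproduces the full fitting route's point estimates exactly (asserted in
the test suite to 1e-10); covariances are skipped since percentile
intervals never use them.

## The synthetic-data generator

`simulate_country()` mirrors the generative form the models assume: log
current smokers follow a polynomial secular trend plus a
level/slope/quadratic break switched on at the country's own ratification
year, with stationary AR(1) Gaussian noise on the log scale
(multiplicative counts); populations grow geometrically; former/ever
smokers follow a log-linear quit ratio with an optional post-ratification
drift. Scenario defaults sit in the ranges the descriptive literature
reports for this setting: baseline prevalences 8–25%, secular declines
near −1%/yr, post-ratification slope changes of a fraction of a percent to
a few percent per year, ratification years 2004–2010 with median 2005,
noise sd 0.02 log points with AR(1) 0.5. The default `"world"` break is
slope-only, −1.5%/yr, giving a −15% cumulative effect at ten years; the
`"tax-split"` preset gives high-tax-change countries roughly twice the
slope change of low-tax-change ones; `"null"` sets all break parameters to
zero.

One deliberate idealization: within a group, countries share the secular
trend coefficients and the break parameters, while baselines, populations,
noise paths, ratification years and quit parameters vary per country.
Sharing makes the group-level log aggregate *exactly* the common polynomial
plus the common break (the country mix only shifts the intercept), so
ground truth is available in closed form and the dual-route truth check
(closed form vs the effects machinery applied to noiseless curves) is
exact. Real country groups are more heterogeneous: their aggregate pre-trend
is only approximately polynomial and their true group effect is a
size-weighted blend. Passing tests therefore demonstrate correctness of the
machinery and calibration under the assumed generative structure — not that
the polynomial family is adequate for any particular real panel.

## Numerical and design choices

- Counts are validated (non-negative, smokers ≤ population, former ≤ ever,
  unique keys) on read and after simulation; zero aggregates are an error
  rather than a silent $-\infty$.
- Group prevalence and quit ratios are ratios of sums, never means of
  ratios.
- The `T` origin (1 at the window start) is cosmetic: trends, trend changes
  and cumulative effects are invariant to shifting it, which the test suite
  checks by refitting on a shifted design.
- The tax-change threshold classifies a rise of exactly 10 percentage
  points as high-tax change; the survey-quality filter is strict
  ("more than" its threshold, default 10).
- Countries without a ratification year, or ratifying too late for a full
  post window, are excluded with a recorded reason; the world grouping
  additionally excludes a configurable list (default `"CHN"`, which is
  analysed separately — its market structure makes it an outlier).
- Windows require complete coverage; the sensitivity options are a longer
  pre-window (e.g. 13 years) and an alternative start rule moving pre-2005
  ratifiers to 2005.
- Problem sizes in the simulation studies (50-country cohorts, 200
  replications, 100 bootstrap replications) were chosen to keep
  Monte-Carlo error small relative to the quantities compared while the
  full suite runs in minutes. At 200 replications the standard error of
  the mean cumulative-effect estimate is about 0.5–0.9 percentage points
  — results of the recovery and null studies should be read at that
  resolution.

## Known limitations

- The polynomial family can misrepresent saturating or plateauing trends;
  nothing in AIC protects against confident extrapolation of a wrong
  family.
- No GLS/ARIMA error models: the design follows OLS + HAC throughout.
- No interpolation of missing years; countries with gaps must be excluded
  upstream.
- The generator does not emulate the survey-smoothing process that
  produces real prevalence panels (smoothing induces serial dependence the
  AR(1) term only approximates), nor sex stratification.
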