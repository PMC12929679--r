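---
title: "Methods: proximity exposure, stratified Poisson GEE, and attributable burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity exposure, stratified Poisson GEE, and attributable burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`proxburden` implements an ecological analysis of mortality versus proximity
to point sources (the motivating application is cancer mortality and nuclear
power plants in U.S. counties): a cumulative inverse-distance exposure metric,
per-stratum Poisson marginal models with cluster-robust inference, and an
attributable-burden calculus. This vignette describes the model, the choices
behind every tunable parameter, what the synthetic-study generator does and
does not emulate, and the package's known limitations.

## The exposure metric

For a county `i` and facility `p` at great-circle distance `d_ip` kilometres
(haversine on a sphere of mean radius 6371.0088 km), the facility contributes
`1/d_ip` (units 1/km) in every calendar year it is operational and 0
otherwise. The operational convention is half-open: a plant contributes for
`start_year <= t < end_year`, so the decommissioning year itself and
everything after contribute 0. Start years are taken inclusive and not
prorated.

Each pair's annual series is then smoothed with a *trailing* mean over
`window_years` consecutive years including the current year. The window is
right-aligned because exposure may not borrow from the future; the smoothing
represents latency — mortality today reflects residence near a plant over the
preceding decade, and a closed plant's contribution should decay rather than
vanish. A consequence worth knowing by heart: after a plant's last
operational year its smoothed contribution declines *linearly* to zero over
exactly `window_years` years.

Finally the smoothed per-plant values are summed over all plants within
`radius_km` of the county centroid, giving the county-year exposure `E_ij`
(1/km). The *equivalent distance* `1/E` is the distance to a single
always-operational plant producing the same metric; it is undefined (returned
as `NA`, never infinity) at `E = 0`.

Defaults: `radius_km = 200`, `window_years = 10`, plant eligibility window
1990–2018 (a plant must be operational at least one year in it). All three
are arguments everywhere they matter. Emitting exposure for year 2000 with a
10-year window requires plant histories from 1991; `trailing_mean()` errors
with the earliest computable year if the history is too short. County
centroids are taken from the input registry as supplied; the package never
derives them from polygons.

Only the `1/d` kernel is provided — no `1/d^2`, no exponential decay — since
the metric under study is exactly the inverse-distance sum.

## The stratified model

Within each of the twelve age–sex strata (six adult age groups, two sexes),
death counts are modelled marginally as

```
log E[deaths_ijk] = b0 + b1 C1_ij + ... + bp Cp_ij + be E_ij + log(pop_ijk)
```

with `i` counties, `j` years, `k` the stratum; the log-population offset puts
coefficients on the rate scale. Estimation is by generalized estimating
equations with Poisson variance, clusters = counties, and an exchangeable
working correlation (any two years of one county share one correlation);
inference uses the robust sandwich covariance, which stays valid when that
working structure is wrong. One model per stratum, never a pooled model with
interactions.

The solver is written against the estimating equations directly. Per
iteration it re-estimates the dispersion and the exchangeable parameter by
the standard moment estimators from Pearson residuals, inverts the working
correlation in closed form (Sherman–Morrison, so the per-cluster work is a
few cross-products), and takes a Fisher-scoring step. Numerical choices:

* starting values from the independence Poisson GLM;
* convergence when the relative coefficient change drops below `1e-8`, with
  a 100-iteration cap; non-convergence is a flagged fit, never silent;
* the exchangeable parameter is clamped inside the invertibility region
  `(-1/(n_max - 1), 1)`;
* rank-deficient designs error naming the collinear columns; a constant-zero
  exposure column is dropped with a flag (the remaining coefficients then
  equal the reduced model's);
* confidence intervals are Wald, `estimate ± z * robust SE`, using
  standard-normal quantiles — with hundreds of county clusters the
  t-versus-z distinction is immaterial, and no small-sample sandwich
  correction is applied so that fits agree exactly with reference GEE
  implementations;
* covariates enter on their raw scale (no internal standardization), and
  exposure enters linearly and untransformed.

With the working correlation forced to independence, the estimating
equations reduce to the Poisson GLM score, and the test suite holds the
solver to that equivalence at `1e-6` relative against `glm()`, as well as to
an independently coded dense estimating-equation oracle for the exchangeable
case. The offset contract — multiplying all populations by `k` shifts only
the intercept, by exactly `-log k` — is also enforced in tests.

## Burden calculus

From a stratum's fitted exposure coefficient `be`, each county-year row gets

* relative risk `RR = exp(E * be)`,
* attributable fraction `AF = (RR - 1)/RR` (negative when `RR < 1`),
* attributable deaths `AF * deaths`.

Uncertainty propagates by substituting the robust Wald CI endpoints of `be`
through `RR -> AF -> cases`. Because `E >= 0`, every step is monotone in
`be`, so endpoint substitution gives exact interval endpoints; stratum and
grand totals sum both the point estimates and the bounds column-wise. This
additive-bounds structure is the one the published stratum table follows (its
printed total bounds equal the column sums of the stratum bounds) and is
deliberately simple — no delta method, no bootstrap. A coefficient CI that
spans zero yields a negative lower burden bound, which is preserved, not
truncated.

`annualize()` divides a period total by the number of study years and rounds
half-up to whole deaths. Note one documented discrepancy: for the 65+ age
groups, the published annualized point estimate is reproduced exactly by this
arithmetic, but the accompanying published annual interval is *not* the sum
of stratum bounds divided by the study years (that gives roughly 2204–6298,
not the printed 3000–9122) and is not derivable from the stratum table by
any simple rule we tested. The package reports endpoint-substitution bounds
and leaves that interval unreproduced.

Reporting curves are emitted as tidy tables so tests target numbers, not
images (`autoplot()` methods are a thin optional layer): the cumulative
population living at or above each proximity level (a non-increasing,
right-continuous step function; population year defaults to the final study
year), and model-predicted `RR(d) = exp(be / d)` against equivalent distance
with an endpoint-substitution band.

## The synthetic-study generator

The real mortality panel cannot be redistributed, so `simulate_study()`
generates complete studies with a known exposure effect, making every
downstream stage testable and the inference machinery falsifiable:

* **Geography.** Counties scatter uniformly over a ~900 × 900 km region;
  400 counties there match the county density of the eastern U.S. Plants
  (default 16, about one per 25 counties, again matching the studied
  region's density) sit 20–80 km from randomly chosen centroids with a
  minimum 15 km separation from every centroid — facilities are sited away
  from population centers — so equivalent distances run from roughly 12 km
  out to the inclusion radius. Start years span 1960–1985; about one plant
  in five decommissions mid-study (2005–2015), exercising the taper.
* **Populations.** Total county population is log-uniform over
  `population_range` (default 5e4–5e5, one decade of heterogeneity);
  stratum populations follow fixed adult age shares split evenly by sex and
  stay constant over years.
* **Rates.** Baseline log death rates per age group default to realistic
  all-cancer mortality magnitudes (from 6e-5 per person-year at 35–44 up to
  4.5e-3 at 85+), with a 1.2× male shift. Three standard-normal county-year
  covariates with modest effects (0.10, −0.08, 0.05) stand in for the
  larger socioeconomic/behavioral adjustment set used with real data, whose
  distributions are not public; both count and effects are configurable.
* **Effect size.** `true_beta_e` defaults to `log(1.2)/0.02 ≈ 9.12`, i.e. a
  county at 50 km equivalent distance has RR 1.2 versus unexposed — the
  magnitude of the largest published stratum relative risks.
* **Correlation.** A county-level normal random effect on the log-rate
  scale (`frailty_sd`, default 0.2) is shared across a county's rows,
  inducing the exchangeable-type within-county correlation the model
  assumes; `frailty_sd = 0` gives independent Poisson rows with
  variance/mean ≈ 1, which the tests verify by Monte Carlo.
* **Determinism.** Every component draws from `set.seed(seed + fixed
  offset)`, so identical configurations reproduce identical studies, and
  each component is individually reproducible.

What the generator does *not* emulate: real U.S. geography and spatial
population clustering, migration and residential history, age–period–cohort
trends, cancer-site-specific latency, spatially correlated confounders, and
exposure measurement error. Passing tests therefore demonstrate that the
machinery is correct and well-calibrated *under the stated generative model*,
not that the substantive findings from real data are unbiased.

## Validation design and problem sizes

The suite validates inference at three scales, chosen as a deliberate
trade-off between statistical resolution and runtime:

* parameter recovery and robust-CI coverage: 200 replicates of a 400-county,
  19-year, single-stratum study with `frailty_sd = 0.2`, holding one
  geography fixed and redrawing covariates, frailty and counts — the
  standard conditional-on-design check for sandwich inference. The coverage
  band asserted is 0.90–0.99 and the mean absolute error tolerance is 1.2
  (about 13% of the true coefficient), registered from a pilot before the
  suite was frozen;
* sensitivity scans: a 250-county single-stratum study with one mid-period
  decommissioning, scanned over 11 radii (200 down to 100 km by 10) and 5
  windows (2, 5, 10, 15, 20 years). Stability is operationalized as: same
  coefficient sign, and 95% CI overlapping the reference configuration's;
  scans report flags rather than hard-failing. When *many* plants close, a
  fitted window that mismatches the generating window misclassifies
  post-closure exposure and attenuates the coefficient — a useful reminder
  that the window is part of the exposure definition, not a nuisance knob;
* a national-scale shape check (~1270 counties × 19 years × 12 strata ≈
  290,000 analysis units) runs generation and panel assembly only.

## Limitations

* The cluster sandwich is first-order: with exposure information
  concentrated in few high-leverage clusters (very close plants, very large
  counties) its SEs bias downward. The generator's defaults keep leverage
  realistic; users simulating more extreme geographies should expect robust
  CIs to undercover somewhat.
* Endpoint substitution propagates only coefficient uncertainty; exposure
  `E` and the death counts themselves are treated as fixed.
* The ecological unit is the county-year stratum; nothing here supports
  individual-level causal statements.
* Counties enter through their supplied centroid; no population weighting
  within counties.
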