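---
title: "Modelling temperature–mortality associations with heatlag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature–mortality associations with heatlag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatlag)
```

## The problem

Daily death counts in a city respond to ambient temperature with a delay:
a hot day raises mortality today and over the following days, and in many
climates unusually cool days do too, so the cumulative exposure–response
function is typically U-, V- or J-shaped with a minimum mortality
temperature (MMT) somewhere in the upper-middle of the local temperature
distribution. heatlag implements the full analysis chain for such studies
in tropical settings with *narrow* temperature ranges (the calibration
target is a city whose daily means span roughly 23.5–33.3 °C with SD about
1.5 °C), where the cold tail is short and the final model often collapses
to a simple "hockey stick" above a single high threshold.

## The model

The core regression is a quasi-Poisson time-series model with log link for
daily counts $Y_t$:

$$\log E(Y_t) = \alpha + \boldsymbol\beta^\top \mathbf{w}_t
  + \mathrm{ns}(t,\ 7/\text{year}) + \mathrm{ns}(\mathrm{RH}_t, 3)
  + \mathrm{dow}_t + \mathrm{hod}_t,$$

with variance $\phi\mu$, dispersion $\phi$ estimated from the Pearson
statistic, and coefficient covariance $\phi\,(X^\top W X)^{-1}$.
$\mathbf{w}_t$ is the DLNM cross-basis: given predictor-space basis
functions $b_j$ (natural cubic spline, hockey-stick threshold, or linear)
and lag-space basis functions $c_k$ over lags $0..L$ (an intercept plus a
natural cubic spline in the lag),

$$w_{t,(j,k)} = \sum_{l=0}^{L} b_j(T_{t-l})\,c_k(l).$$

Cumulative effects follow by contrast: the log relative risk of
temperature $x$ versus a reference $x_0$, summed over the lag window, is
$\sum_{j,k}\beta_{jk}\,[b_j(x)-b_j(x_0)]\sum_l c_k(l)$, with delta-method
standard errors and Wald 95% intervals on the log scale. Lag-specific
contrasts replace $\sum_l c_k(l)$ by $c_k(l)$; cumulative log RR is
exactly the sum of the lag-specific ones, and the package asserts this
identity in its tests.

The natural cubic spline uses the restricted-cubic truncated-power
parameterization (columns $x$ and $d_k(x) - d_{K-1}(x)$ with
$d_k(x) = [(x-\xi_k)_+^3 - (x-\xi_K)_+^3]/(\xi_K-\xi_k)$), which is exactly
linear beyond the boundary knots. Knots sit at equally spaced quantiles of
the data (type-7 rule) and are frozen in a serializable `basis_spec`, so
prediction-time evaluation reuses the fit-time knots; published knot
positions can be plugged in directly.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pred_df` | 4 | NCS columns in temperature space |
| `lag_df` | 2 | NCS columns in lag space (plus an intercept column) |
| `max_lag` | 13 days | lag window $L$; reported lag effects in this literature sit within 0–5 days, 13 leaves margin |
| `trend_df_per_year` | 7 | seasonal/trend control density, the conventional choice for daily mortality series |
| `rh_df` | 3 | humidity spline |
| `mmt_window` | 10th–90th pctl | MMT search window; spline tails are variance-inflated, and an interior MMT is the quantity of interest |
| `percentiles` | 1, 5, 95, 99 | RR reporting points |

Grid steps are 0.1 °C throughout (curves, MMT, threshold search), finer
than the 0.1 °C precision at which MMTs and thresholds are conventionally
reported. The 95% multiplier is fixed at 1.96.

## Model simplification

`run_transition()` reproduces the objective spline-to-threshold
simplification in three stages: (1) the flexible NCS-NCS fit and its MMT;
(2) thresholds placed at the interior local minima of the stage-1 curve
(two or more minima give a double-threshold DTHR model with a closed null
region between the arms; a single minimum goes straight to a single high
threshold, STHR); (3) a 0.1 °C grid search around the stage-2 thresholds,
clipped to the 1st–99th percentile range. Candidates are scored by QAIC,
$-2\,\ell/\phi_{\mathrm{ref}} + 2\,\mathrm{rank}$ with
$\phi_{\mathrm{ref}}$ from the richest (stage-1) model; deviance explained
($1 - D/D_0$) is computed alongside, since the literature's exact
selection criterion across such steps is not standardized — both are
logged so either convention can be matched. "Minimizing the lower
temperature effect" is operationalized explicitly: among candidates within
2 QAIC of the optimum (0.005 when selecting on deviance explained), the
model whose cold-arm slope is closest to null wins, so an STHR model —
which has no cold arm — is selected whenever it is competitive. All stages
share `max_lag`, hence identical usable rows, making the criteria
comparable.

A caveat worth stating: the slope SE of a threshold model refitted at a
*searched* threshold is conditional on that threshold. Threshold-selection
noise propagates into the slope (selected thresholds above the true kink
bias the slope up, below it down), so post-selection intervals are
anti-conservative; the package's validation therefore checks slope
calibration at a fixed threshold and threshold recovery separately.

## Season-specific models

Season blocks from different years are not one continuous series, so the
season analysis changes estimator rather than subsetting naively: the
cross-basis (and hence every lagged exposure) is computed on the full
continuous series *first*, and only then are rows partitioned by the
PAGASA seasons (DJF, MAM, JJA, SON — a pure function of month). Within
each season, ordinary least squares is run on the log-transformed count,
$\log(Y + 1)$ by default (configurable to $+0.5$; the shift guards
categories whose daily minimum is 0), against the cross-basis block, a
within-season day-of-year NCS (4 df), a within-season trend NCS (3 df),
the humidity NCS (3 df), day-of-week and holiday terms. "$\log E(Y')$
with an already log-transformed response" is internally inconsistent as
sometimes printed; Gaussian OLS on the log count is the standard reading
and is the assumption made here. Effects are exponentiated contrasts —
an RR-analogue, since the response is a log count — and per-degree
"season slopes" are contrasts between two anchor temperatures (by default
the season's 75th and 99th percentiles, or the threshold and threshold+1
when a threshold basis is configured).

Within-season day-of-year is counted from the start of each contiguous
seasonal block, so DJF wraps the year boundary as one block; this keeps
the 4-df seasonal spline well defined.

## The synthetic-data generator

`simulate_dataset()` is the package's ground-truth instrument, not a test
fixture: temperature is a seasonal sinusoid plus stationary AR(1) noise
(defaults: mean 28.8 °C, amplitude 1.4 °C, AR(1) 0.7, innovation SD
0.82 °C, giving marginal SD ≈ 1.5 and range ≈ 24–33.5), humidity is
analogous around 73.9%, and counts follow the mortality model forward:
baseline 52/day, mild day-of-week multipliers, a seasonal nuisance cycle
in the log mean (on by default — the trend spline exists to absorb
exactly this confounding, and a generator without it would not exercise
that control), a configurable true exposure-lag-response surface
(null / single threshold / double threshold / U-shape, each a
predictor-space shape times a normalized lag profile, optionally gated by
season multipliers for effect-modification studies), and gamma-Poisson
mixing calibrated so that the variance/mean ratio equals the configured
$\omega$ — the quasi-Poisson estimand directly. Category counts are a
multinomial split of the overdispersed total with day-specific
probabilities proportional to each category's mean, so they sum to the
total exactly while supporting per-category slope multipliers. Seeds are
consumed in named substreams (weather, counts, split) so changing one
component cannot silently shift another's draws.

What the generator does *not* emulate: real series carry influenza and
typhoon episodes, holiday reporting artefacts, long-term demographic
drift, and pollution co-exposures. Passing recovery tests on this
generator demonstrates that the estimators are correct under the stated
model, not that the model is adequate for any particular city's data.

## Numerical choices and degenerate inputs

IRLS runs to a relative deviance tolerance of 1e-9 (max 50 iterations);
dispersion uses the Pearson statistic; rank deficiency is an error naming
the collinear columns rather than silent aliasing. Thresholds contribute
zero at the threshold itself (closed null region), making RR exactly 1
there. MMT ties break toward the lowest temperature; flat curves return
the window midpoint with a warning. Date gaps are a hard error (lagged
exposure requires contiguity); an explicit `allow_gaps` mode splits the
series instead of imputing. Constant humidity drops the humidity spline
with a warning; an all-zero category is skipped with a warning. Zero
counts are legal everywhere (the season model's log shift handles them).

## Validation scale

The package's own validation (its test suite) runs the recovery studies
at the generating conditions — 5-year series, ~52 deaths/day,
overdispersion 1.5 — with 100 replicates for parameter-recovery checks
and 500 for coverage/size checks, and uses the truth's lag support with a
saturated lag basis in those studies so that lag-space misspecification
does not confound the statistical property being measured. Coverage of
the 95% interval for the cumulative RR at the 99th percentile lands
within 90–98%, the null-surface exclusion rate at the 99th percentile
within 2–8%, threshold recovery within 0.5 °C median error, and U-shape
MMT recovery within 1 °C median error; `scripts/acceptance.R` recomputes
a single-run version of these quantities from scratch.

## Known limitations

- No penalized splines, B-spline alternatives, negative-binomial
  likelihood, GAM/GEE estimation, or attributable-fraction computation.
- Post-selection inference after the threshold grid search is conditional
  (see above).
- The holiday calendar is study-specific and must be supplied; it
  defaults to empty.
- No offset/population term: counts, not rates, are modelled, which
  assumes a stable population over the study window.
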