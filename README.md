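# heatlag

Distributed-lag nonlinear modelling of temperature–mortality associations
in daily time series, aimed at tropical cities with narrow temperature
ranges, where the exposure–response curve often simplifies to a
"hockey stick" above a single high threshold.

The package is for environmental epidemiologists and biostatisticians who
have (or want to prototype against) a daily table of mean temperature,
relative humidity and death counts, and who need: cumulative and
lag-specific relative risks with delta-method confidence intervals, the
minimum mortality temperature (MMT), percentile RR tables stratified by
cause/sex/age category, an objective spline-to-threshold model
simplification, and season-specific effect-modification analyses — plus a
calibrated synthetic-data generator with known ground truth to validate
every step.

## The model

Daily counts $Y_t$ follow a quasi-Poisson regression with log link:

$$\log E(Y_t) = \alpha + \boldsymbol\beta^\top\mathbf{w}_t
 + \mathrm{ns}(t,\,7/\mathrm{yr}) + \mathrm{ns}(\mathrm{RH}_t,3)
 + \mathrm{dow}_t + \mathrm{hod}_t,\qquad \mathrm{Var} = \phi\,\mu ,$$

where $\mathbf{w}_t$ is a DLNM cross-basis over temperature and lag:
$w_{t,(j,k)} = \sum_{l=0}^{L} b_j(T_{t-l})\,c_k(l)$, with $b_j$ a natural
cubic spline, threshold ("hockey-stick") or linear basis in temperature
and $c_k$ an intercept-plus-spline basis in the lag. Cumulative log RR of
temperature $x$ versus reference $x_0$ is the contrast
$\sum_{j,k}\beta_{jk}[b_j(x)-b_j(x_0)]\sum_l c_k(l)$; the MMT is the
argmin of the fitted curve, and RRs are reported at the 1st/5th/95th/99th
percentile temperatures relative to it. A three-stage procedure
(flexible spline → thresholds at the curve's minima → threshold grid
search scored by QAIC) reduces the model to its simplest adequate form.
Season-specific associations are estimated by OLS on log counts with
within-season calendar controls, with lags computed on the full
continuous series before season subsetting.

## Worked example

Simulate five Manila-like years with a known single-high-threshold truth
(threshold 30 °C, cumulative slope log 1.10 per °C, overdispersion 1.5)
and run the pipeline:

```r
library(heatlag)
cfg <- synth_config(mortality = list(overdispersion = 1.5))
ds  <- simulate_dataset(cfg, seed = 42)

res <- run_category_analysis(ds$series, "all",
                             config = list(max_lag = 4, lag_df = 4))
print(res)
#> Category-stratified temperature-mortality analysis
#>   max lag: 4 days; categories: all
#>   category percentile temperature    rr ci_low ci_high  mmt
#> 1      all          1        25.4 0.953  0.890    1.02 26.9
#> 2      all          5        26.4 0.988  0.972    1.00 26.9
#> 3      all         95        31.4 1.118  1.071    1.17 26.9
#> 4      all         99        32.7 1.308  1.217    1.40 26.9
```

The RR rises only above the threshold: 1.31 (95% CI 1.22–1.40) at the
99th percentile temperature (32.7 °C), against a truth of
$1.10^{32.7-30} \approx 1.29$, while the 1st/5th-percentile RRs sit at 1
(the truth below 30 °C is flat; the MMT of 26.9 °C is noise within that
flat region). The simplification procedure then recovers the generating
threshold:

```r
tr <- run_transition(ds$series, config = list(max_lag = 4, lag_df = 4,
                                              category = "all"))
print(tr)
#> Model-simplification transition report
#>   NCS-NCS            QAIC   8761.19  dev.expl 0.121  MMT 26.9
#>   STHR-NCS (minima)  QAIC   8762.06  dev.expl 0.106  thresholds [29.459338096528]
#>   STHR-NCS (searched) QAIC   8752.22  dev.expl 0.111  thresholds [30.259338096528]
#>   selected: STHR-NCS (searched)
```

The searched single-high-threshold model (30.3 °C, within the 0.1 °C grid
of the true 30.0) beats the flexible spline by ~9 QAIC. Season-specific
analysis (`run_season_analysis`) and the config-driven writers
(`cmd_simulate`, `cmd_fit`, `cmd_simplify`, `cmd_seasons`; see also
`inst/scripts/heatlag-cli.R`) complete the pipeline.

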