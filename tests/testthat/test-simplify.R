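curve_of <- function(grid, y) {
  structure(list(grid = grid, log_rr = y), class = "exposure_curve")
}

test_that("local minima detection handles W, U, monotone and plateau shapes", {
  g <- seq(24, 33, by = 0.1)
  w <- pmin((g - 26)^2, (g - 30)^2 + 0.01)
  expect_equal(locate_minima(curve_of(g, w)), c(26.0, 30.0))
  expect_equal(locate_minima(curve_of(g, (g - 29)^2)), 29.0)
  expect_equal(locate_minima(curve_of(g, g)), numeric(0))
  # plateau collapses to its lowest temperature
  plat <- pmax(abs(g - 28) - 0.5, 0)
  expect_equal(locate_minima(curve_of(g, plat)), 27.5)
})

test_that("threshold models are structurally flat inside the null region", {
  ds <- simulate_dataset(small_sthr_config(), seed = 41)
  m <- fit_threshold_model(ds$series, threshold_spec(high = 30),
                           config = list(max_lag = 7, category = "all"))
  cv <- m$curve
  below <- cv$grid <= 30
  expect_lt(max(abs(cv$log_rr[below])), 1e-12)
  # log-linear above: second differences vanish
  above <- cv$log_rr[cv$grid >= 30]
  expect_lt(max(abs(diff(above, differences = 2))), 1e-8)
  expect_equal(m$slopes$arm, "heat")
  expect_error(fit_threshold_model(ds$series, threshold_spec(high = 50),
                                   config = list(max_lag = 7)),
               "outside the observed temperature range")
})

test_that("a noiseless log-linear heat effect is recovered exactly", {
  # deterministic limit: fit the exact mean counts (no sampling noise) with
  # a correctly specified same-day threshold model
  cfg <- small_sthr_config(heat_slope = log(1.2))
  cfg$mortality$dow_multipliers <- rep(1, 7)
  cfg$mortality$seasonal_amplitude <- 0
  cfg$surface$lag_weights <- 1  # all effect at lag 0
  ds <- simulate_dataset(cfg, seed = 42)
  s <- ds$series
  cb <- build_crossbasis(s$tmean, basis_spec("sthr", thresholds = list(high = 30)),
                         lag_spec = NULL, max_lag = 0)
  des <- assemble_design(s, cb, derive_calendar_covariates(s))
  # the quasi-likelihood mean structure accepts the non-integer exact means
  fit <- fit_quasipoisson(ds$truth$expected[des$usable], des$X,
                          cb_cols = des$cb_cols)
  sl <- heatlag:::threshold_slopes(fit, cb, list(high = 30))
  expect_equal(sl$slope[1], log(1.2), tolerance = 1e-6)
})

test_that("null-truth double-threshold arms estimate zero slopes", {
  ds <- simulate_dataset(small_null_config(), seed = 43)
  m <- fit_threshold_model(ds$series, threshold_spec(low = 27, high = 30),
                           config = list(max_lag = 7, category = "all"))
  for (i in seq_len(nrow(m$slopes))) {
    expect_lt(abs(m$slopes$slope[i]) / m$slopes$se[i], 2.5)
  }
})

test_that("a degenerate single-candidate search returns that candidate", {
  ds <- simulate_dataset(small_sthr_config(), seed = 44)
  res <- threshold_grid_search(ds$series, candidate_highs = 30.3,
                               config = list(max_lag = 7, category = "all"))
  expect_equal(res$spec$high, 30.3)
  expect_null(res$spec$low)
  expect_equal(nrow(res$trace), 1)
  expect_error(threshold_grid_search(ds$series, candidate_highs = numeric(0)),
               "empty candidate grid")
})

test_that("the transition report is internally consistent on threshold-truth data", {
  ds <- simulate_dataset(small_sthr_config(), seed = 45)
  tr <- run_transition(ds$series, config = list(max_lag = 7, category = "all"))
  expect_s3_class(tr, "transition_report")
  expect_length(tr$stages, 3)
  # all stages share the same usable rows, so criteria are comparable
  ns <- vapply(tr$stages, function(s) length(s$fit$y), 1L)
  expect_true(all(ns == ns[1]))
  # threshold-stage curves are centered so RR = 1 at their high threshold
  for (i in 2:3) {
    s <- tr$stages[[i]]
    j <- which.min(abs(s$curve$grid - s$thresholds$high))
    expect_equal(s$curve$rr[j], 1, tolerance = 1e-8)
  }
  # reproducibility of the search under identical input
  tr2 <- run_transition(ds$series, config = list(max_lag = 7, category = "all"))
  expect_equal(tr2$stages[[3]]$thresholds$high, tr$stages[[3]]$thresholds$high)
  expect_output(print(tr), "Model-simplification")
})
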