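# One moderately sized fitted model shared across the effect tests.
fit_fixture <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      ds <- simulate_dataset(small_sthr_config(), seed = 31)
      res <- run_category_analysis(ds$series, "all", config = list(max_lag = 7))
      value <<- list(ds = ds, res = res)
    }
    value
  }
})

test_that("the curve is exactly 1 with a degenerate CI at the reference", {
  res <- fit_fixture()$res
  cv <- res$curves$all
  i <- which.min(abs(cv$grid - cv$ref))
  expect_equal(cv$rr[i], 1, tolerance = 1e-10)
  expect_equal(cv$se[i], 0, tolerance = 1e-10)
  expect_true(all(cv$ci_low <= cv$rr + 1e-12 & cv$rr <= cv$ci_high + 1e-12))
  expect_equal(cv$rr, exp(cv$log_rr))
})

test_that("re-centering shifts the log curve by a constant", {
  fx <- fit_fixture()
  fit <- fx$res$fits$all
  cb <- fx$res$cb
  grid <- seq(26, 32, by = 0.5)  # inside the boundary, contains both refs
  c1 <- predict_curve(fit, cb, grid = grid, ref = 27)
  c2 <- predict_curve(fit, cb, grid = grid, ref = 30)
  shift <- c1$log_rr - c2$log_rr
  expect_lt(max(abs(shift - shift[1])), 1e-10)
  expect_equal(shift[1], c1$log_rr[grid == 30], tolerance = 1e-10)
  # points beyond the boundary knots are flagged as extrapolation
  expect_warning(predict_curve(fit, cb, grid = c(20, 28), ref = 28),
                 "extrapolation")
})

test_that("delta-method SEs match a Monte-Carlo oracle", {
  fx <- fit_fixture()
  fit <- fx$res$fits$all
  cb <- fx$res$cb
  temps <- c(25, 31.5, 32.5)
  cv <- predict_curve(fit, cb, grid = temps, ref = 28)
  set.seed(32)
  beta <- fit$coefficients[fit$cb_cols]
  V <- fit$vcov[fit$cb_cols, fit$cb_cols]
  ch <- chol(V)
  draws <- matrix(rnorm(10000 * length(beta)), 10000) %*% ch
  draws <- sweep(draws, 2, beta, "+")
  M <- t(sapply(temps, function(tt) {
    crossbasis_contrast(cb$pred_spec, cb$lag_spec, cb$max_lag, tt, 28)
  }))
  mc_se <- apply(draws %*% t(M), 2, sd)
  expect_lt(max(abs(mc_se - cv$se) / cv$se), 0.05)
})

test_that("MMT search follows the grid-argmin, tie and flatness rules", {
  grid <- seq(23.5, 33.3, by = 0.1)
  quad <- structure(list(grid = grid, log_rr = (grid - 30)^2), class = "exposure_curve")
  expect_equal(find_mmt(quad), 30.0)

  twomin <- structure(list(grid = grid,
                           log_rr = pmin((grid - 26)^2, (grid - 30)^2)),
                      class = "exposure_curve")
  expect_equal(find_mmt(twomin), 26.0)

  flat <- structure(list(grid = grid, log_rr = rep(0.2, length(grid))),
                    class = "exposure_curve")
  expect_warning(mm <- find_mmt(flat), "flat")
  expect_equal(mm, mean(range(grid)))
  expect_equal(find_mmt(quad, window = c(31, 33.3)), 31.0)
})

test_that("percentile RR rows interpolate the MMT-centered curve", {
  fx <- fit_fixture()
  res <- fx$res
  cv <- res$curves$all
  x <- fx$ds$series$tmean
  # a pseudo-percentile exactly at the MMT gives RR 1
  at_mmt <- rr_at_percentiles(cv, rep(cv$mmt, 5), percentiles = 50)
  expect_equal(at_mmt$rr, 1, tolerance = 1e-9)
  tab <- res$table
  # monotone passthrough above the MMT for this heat-only truth
  expect_gte(tab$rr[tab$percentile == 99], tab$rr[tab$percentile == 95])
  expect_true(all(tab$mmt == res$mmt["all"]))
})

test_that("category analyses are independent and guard degenerate input", {
  fx <- fit_fixture()
  ds <- fx$ds
  res2 <- run_category_analysis(ds$series, c("adult", "elderly"),
                                config = list(max_lag = 7))
  solo <- run_category_analysis(ds$series, "elderly", config = list(max_lag = 7))
  expect_equal(res2$fits$elderly$coefficients, solo$fits$elderly$coefficients)

  expect_error(run_category_analysis(ds$series, character(0)), "empty")

  s0 <- ds$series
  s0$adult <- 0L
  expect_warning(r0 <- run_category_analysis(s0, c("adult", "elderly"),
                                             config = list(max_lag = 7)),
                 "all-zero")
  expect_equal(names(r0$curves), "elderly")
})
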