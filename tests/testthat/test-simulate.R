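test_that("generation is deterministic in (config, seed)", {
  cfg <- small_sthr_config()
  d1 <- simulate_dataset(cfg, seed = 61)
  d2 <- simulate_dataset(cfg, seed = 61)
  expect_identical(as.data.frame(d1$series), as.data.frame(d2$series))
  d3 <- simulate_dataset(cfg, seed = 62)
  expect_false(identical(d1$series$all, d3$series$all))
})

test_that("degenerate weather settings give a constant series", {
  cfg <- synth_config(n_years = 1,
                      temp = list(amplitude = 0, innovation_sd = 0))
  w <- generate_weather(cfg, seed = 63)
  expect_equal(w$tmean, rep(28.8, nrow(w)))
  expect_error(synth_config(temp = list(ar1 = 1)), "ar1")
})

test_that("weather moments match the configured process", {
  cfg <- synth_config(n_years = 5)
  w <- generate_weather(cfg, seed = 64)
  expect_lt(abs(mean(w$tmean) - 28.8), 0.15)
  # stationary SD: sqrt(amplitude^2/2 + innovation_sd^2/(1 - ar1^2))
  target_sd <- sqrt(cfg$temp$amplitude^2 / 2 +
                    cfg$temp$innovation_sd^2 / (1 - cfg$temp$ar1^2))
  expect_lt(abs(sd(w$tmean) - target_sd) / target_sd, 0.15)
  expect_true(all(w$rh > 0 & w$rh <= 100))
})

test_that("the truth surface evaluates in closed form", {
  su <- truth_surface("sthr", threshold_high = 30, heat_slope = log(1.10),
                      lag_weights = c(1))
  expect_equal(true_surface_logrr(su, 32, 0), 2 * log(1.10))
  expect_equal(true_surface_logrr(su, 28, 0), 0)
  expect_equal(true_surface_logrr(truth_surface("null"), 40, 0), 0)

  # cumulative log RR equals slope * excess for any normalized lag profile
  su2 <- truth_surface("sthr", threshold_high = 30, heat_slope = log(1.10),
                       lag_weights = c(3, 2, 1))
  cum <- sum(sapply(0:5, function(l) true_surface_logrr(su2, 31.7, l)))
  expect_equal(cum, log(1.10) * 1.7)

  # u-shape: derivative at the reference heat point equals the given slope
  su3 <- truth_surface("ushape", mmt = 29, heat_slope = log(1.10))
  eps <- 1e-6
  d <- (heatlag:::cumulative_truth(su3, 32 + eps) -
        heatlag:::cumulative_truth(su3, 32 - eps)) / (2 * eps)
  expect_equal(d, log(1.10), tolerance = 1e-6)
  expect_equal(heatlag:::cumulative_truth(su3, 29), 0)
})

test_that("counts are calibrated: baseline mean, overdispersion, shares, conservation", {
  cfg0 <- synth_config(n_years = 5, surface = truth_surface("null"),
                       mortality = list(dow_multipliers = rep(1, 7),
                                        seasonal_amplitude = 0,
                                        overdispersion = 1))
  ds0 <- simulate_dataset(cfg0, seed = 65)
  expect_lt(abs(mean(ds0$series$all) - 52) / 52, 0.02)

  # omega = 2: variance/mean ratio of the generated counts near 2
  cfgo <- synth_config(n_years = 27.4,  # ~10000 days
                       surface = truth_surface("null"),
                       mortality = list(dow_multipliers = rep(1, 7),
                                        seasonal_amplitude = 0,
                                        overdispersion = 2))
  dso <- simulate_dataset(cfgo, seed = 66)
  ratio <- var(dso$series$all) / mean(dso$series$all)
  expect_gt(ratio, 1.7); expect_lt(ratio, 2.3)

  # category shares and exact conservation
  cfgs <- synth_config(n_years = 5, surface = truth_surface("null"),
                       cats = data.frame(name = c("a", "b"),
                                         share = c(0.6, 0.4),
                                         mult = c(1, 1)))
  dss <- simulate_dataset(cfgs, seed = 67)
  expect_identical(dss$series$a + dss$series$b, dss$series$all)
  expect_lt(abs(sum(dss$series$a) / sum(dss$series$all) - 0.6), 0.02)

  expect_error(synth_config(cats = data.frame(name = "a", share = 0.5, mult = 1)),
               "sum to 1")
  expect_error(synth_config(mortality = list(overdispersion = 0.5)), ">= 1")
})

test_that("the generator raises on exploding means", {
  cfg <- synth_config(n_years = 1,
                      surface = truth_surface("sthr", threshold_high = 24,
                                              heat_slope = 8))
  expect_error(simulate_dataset(cfg, seed = 68), "overflow|slopes")
})
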