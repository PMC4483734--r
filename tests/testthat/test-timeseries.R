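test_that("CSV read-back returns the series that was written", {
  tf <- tempfile(fileext = ".csv")
  df <- write_tiny_csv(tf, n = 5)
  s <- read_timeseries(tf)
  expect_s3_class(s, "mortality_ts")
  expect_equal(nrow(s), 5)
  expect_equal(s$tmean, df$tmean)
  expect_equal(s$all, df$all)
  expect_equal(categories(s), "all")

  # write_timeseries is the exact inverse
  tf2 <- tempfile(fileext = ".csv")
  write_timeseries(s, tf2)
  s2 <- read_timeseries(tf2)
  expect_equal(as.data.frame(s2), as.data.frame(s))
})

test_that("validation rejects gaps, duplicates and bad counts", {
  tf <- tempfile(fileext = ".csv")
  df <- write_tiny_csv(tf, n = 4)

  gap <- df[-3, ]  # drop 2006-01-03
  write.csv(gap, tf, row.names = FALSE, quote = FALSE)
  expect_error(read_timeseries(tf), "gap between 2006-01-02 and 2006-01-04")

  dup <- df; dup$date[2] <- dup$date[1]
  write.csv(dup, tf, row.names = FALSE, quote = FALSE)
  expect_error(read_timeseries(tf), "duplicate|increasing")

  neg <- df; neg$all[2] <- -1L
  write.csv(neg, tf, row.names = FALSE, quote = FALSE)
  expect_error(read_timeseries(tf), "negative count at row 2")

  frac <- df; frac$all[3] <- 2.5
  write.csv(frac, tf, row.names = FALSE, quote = FALSE)
  expect_error(read_timeseries(tf), "non-integer")

  noth <- df; names(noth)[2] <- "temp"
  write.csv(noth, tf, row.names = FALSE, quote = FALSE)
  expect_error(read_timeseries(tf), "missing required column: tmean")
})

test_that("allow_gaps splits the series instead of imputing", {
  tf <- tempfile(fileext = ".csv")
  df <- write_tiny_csv(tf, n = 5)
  write.csv(df[-3, ], tf, row.names = FALSE, quote = FALSE)
  parts <- read_timeseries(tf, allow_gaps = TRUE)
  expect_length(parts, 2)
  expect_equal(vapply(parts, nrow, 1L), c(2L, 2L))
})

test_that("PAGASA season mapping is exact, exhaustive and disjoint", {
  expect_equal(as.character(classify_season("2006-01-15")), "DJF")
  expect_equal(as.character(classify_season("2007-04-01")), "MAM")
  expect_equal(as.character(classify_season("2010-12-31")), "DJF")
  expect_equal(as.character(classify_season("2008-07-04")), "JJA")
  expect_equal(as.character(classify_season("2008-10-01")), "SON")

  # every day of a leap and a non-leap year maps to exactly one label
  for (yr in c("2007", "2008")) {
    days <- seq(as.Date(paste0(yr, "-01-01")), as.Date(paste0(yr, "-12-31")), "day")
    sn <- classify_season(days)
    expect_false(anyNA(sn))
    expect_equal(sum(table(sn)), length(days))
  }
})

test_that("calendar covariates follow the fixed conventions", {
  s <- tiny_series(10)  # starts Sunday 2006-01-01
  cov <- derive_calendar_covariates(s, holidays = as.Date("2006-01-01"))
  expect_equal(as.integer(as.character(cov$dow[2])), 0L)  # 2006-01-02 is a Monday
  expect_equal(cov$hod, c(1L, rep(0L, 9)))
  expect_equal(cov$time_index, 0:9)
  expect_equal(cov$doy[1], 1L)

  cov0 <- derive_calendar_covariates(s)
  expect_true(all(cov0$hod == 0L))
  expect_warning(derive_calendar_covariates(s, holidays = as.Date("2012-01-01")),
                 "outside series range")
})

test_that("summary statistics use the fixed type-7 percentile rule", {
  n <- 11
  s <- mortality_ts(seq(as.Date("2006-01-01"), by = "day", length.out = n),
                    tmean = rep(28.8, n), rh = rep(75, n),
                    deaths = data.frame(all = 1:11))
  tab <- summary_statistics(s)
  tm <- tab[tab$variable == "tmean", ]
  expect_equal(tm$mean, 28.8)
  expect_equal(tm$sd, 0)
  expect_equal(unlist(tm[c("p10", "p50", "p90")]), rep(28.8, 3),
               ignore_attr = TRUE)
  expect_equal(tab[tab$variable == "all", "p50"], 6)

  tab2 <- summary_statistics(s, by_season = TRUE)
  expect_true("DJF" %in% tab2$season)
  expect_error(summary_statistics(s[0, ]), "empty")
})

test_that("generated temperatures reproduce the configured climate", {
  ds <- simulate_dataset(synth_config(n_years = 5), seed = 11)
  expect_equal(nrow(ds$series), 1826)
  expect_lt(abs(mean(ds$series$tmean) - 28.8), 0.15)
})
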