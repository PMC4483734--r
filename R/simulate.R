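#' Define a true exposure-lag-response surface
#'
#' The generator's ground truth is separable: a predictor-space shape f(T)
#' times a normalized lag profile w_l, so the cumulative (lag-summed) log RR
#' at temperature T is exactly f(T). Kinds:
#' \describe{
#'   \item{`null`}{f identically 0.}
#'   \item{`sthr`}{`f(T) = heat_slope * max(0, T - threshold_high)`.}
#'   \item{`dthr`}{adds a cold arm
#'     `cold_slope * max(0, threshold_low - T)`.}
#'   \item{`ushape`}{`f(T) = curv * (T - mmt)^2` with the curvature set so
#'     the derivative at `t_ref_heat` (default `mmt + 3`) equals
#'     `heat_slope`.}
#' }
#'
#' @param kind surface kind.
#' @param mmt minimum of the u-shape (degrees C).
#' @param threshold_high,threshold_low thresholds (degrees C).
#' @param heat_slope,cold_slope log RR per degree C beyond the respective
#'   threshold (u-shape: derivative at `t_ref_heat`).
#' @param lag_weights non-negative weights over lags 0..L; normalized to
#'   sum to 1.
#' @param t_ref_heat reference temperature for the u-shape slope.
#' @param season_multipliers optional named multipliers (DJF/MAM/JJA/SON)
#'   gating the surface by season; default all 1 (no effect modification).
#' @return object of class `truth_surface`.
#' @export
truth_surface <- function(kind = c("null", "sthr", "dthr", "ushape"),
                          mmt = NULL, threshold_high = NULL, threshold_low = NULL,
                          heat_slope = 0, cold_slope = 0,
                          lag_weights = c(0.4, 0.3, 0.15, 0.1, 0.05),
                          t_ref_heat = NULL,
                          season_multipliers = c(DJF = 1, MAM = 1, JJA = 1, SON = 1)) {
  kind <- match.arg(kind)
  if (any(lag_weights < 0)) stop("lag weights must be non-negative")
  if (sum(lag_weights) <= 0) stop("lag weights must not be all zero")
  lag_weights <- lag_weights / sum(lag_weights)
  if (kind == "null") { heat_slope <- 0; cold_slope <- 0 }
  if (kind == "sthr" && is.null(threshold_high)) stop("sthr surface needs threshold_high")
  if (kind == "dthr" && (is.null(threshold_high) || is.null(threshold_low))) {
    stop("dthr surface needs both thresholds")
  }
  if (kind == "ushape") {
    if (is.null(mmt)) stop("ushape surface needs mmt")
    if (is.null(t_ref_heat)) t_ref_heat <- mmt + 3
  }
  structure(list(kind = kind, mmt = mmt, threshold_high = threshold_high,
                 threshold_low = threshold_low, heat_slope = heat_slope,
                 cold_slope = cold_slope, lag_weights = lag_weights,
                 t_ref_heat = t_ref_heat,
                 season_multipliers = season_multipliers),
            class = "truth_surface")
}

# Cumulative (lag-summed) true log RR at temperature T versus the null region.
cumulative_truth <- function(surface, temp) {
  switch(surface$kind,
    null = rep(0, length(temp)),
    sthr = surface$heat_slope * pmax(0, temp - surface$threshold_high),
    dthr = surface$heat_slope * pmax(0, temp - surface$threshold_high) +
      surface$cold_slope * pmax(0, surface$threshold_low - temp),
    ushape = {
      curv <- surface$heat_slope / (2 * (surface$t_ref_heat - surface$mmt))
      curv * (temp - surface$mmt)^2
    }
  )
}

#' True log-RR contribution of one (temperature, lag) cell
#'
#' `f(temp) * w_lag`; lags beyond the profile support contribute 0. Because
#' the weights sum to 1, summing over lags returns exactly f(temp).
#'
#' @param surface a `truth_surface`.
#' @param temp temperature(s), degrees C.
#' @param lag lag day (scalar).
#' @return numeric vector of log-RR contributions.
#' @export
true_surface_logrr <- function(surface, temp, lag) {
  w <- if (lag >= 0 && lag < length(surface$lag_weights)) {
    surface$lag_weights[lag + 1L]
  } else 0
  cumulative_truth(surface, temp) * w
}

#' Synthetic-data configuration
#'
#' Defaults are calibrated to the Manila City 2006-2010 study conditions:
#' daily mean temperature with mean 28.8 degrees C, a small seasonal cycle
#' and AR(1) day-to-day persistence giving a marginal SD near 1.5 and a
#' range of roughly 23.5-33.3; relative humidity with mean 73.9 and SD
#' near 7.5; all-cause mortality around 52 deaths/day with mild day-of-week
#' structure, a seasonal nuisance cycle in the log mean (which the trend
#' spline must absorb), and quasi-Poisson overdispersion.
#'
#' @param n_years series length in years (default 5).
#' @param start first date.
#' @param temp list: `mean`, `amplitude` (seasonal, degrees C), `phase`
#'   (day of year offset), `ar1`, `innovation_sd`.
#' @param rh list: `mean`, `amplitude`, `phase`, `ar1`, `innovation_sd`.
#' @param mortality list: `baseline` (deaths/day), `dow_multipliers`
#'   (length 7, Monday first), `overdispersion` (variance/mean ratio
#'   omega >= 1), `seasonal_amplitude` (log scale), `seasonal_phase`.
#' @param surface a `truth_surface`.
#' @param cats data frame with `name`, `share`, `mult` (per-category
#'   multiplier on the true log-RR surface); shares must sum to 1.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_years = 5,
                         start = "2006-01-01",
                         temp = list(),
                         rh = list(),
                         mortality = list(),
                         surface = truth_surface("sthr", threshold_high = 30,
                                                 heat_slope = log(1.10)),
                         cats = data.frame(name = c("adult", "elderly"),
                                           share = c(0.679, 0.321),
                                           mult = c(1, 1))) {
  temp_d <- list(mean = 28.8, amplitude = 1.4, phase = 30, ar1 = 0.7,
                 innovation_sd = 0.82)
  rh_d <- list(mean = 73.9, amplitude = 5, phase = 210, ar1 = 0.6,
               innovation_sd = 4.5)
  mort_d <- list(baseline = 52,
                 dow_multipliers = c(0.99, 1.00, 1.00, 1.01, 1.02, 1.00, 0.98),
                 overdispersion = 1.2,
                 seasonal_amplitude = 0.03, seasonal_phase = 330)
  for (nm in names(temp)) temp_d[[nm]] <- temp[[nm]]
  for (nm in names(rh)) rh_d[[nm]] <- rh[[nm]]
  for (nm in names(mortality)) mort_d[[nm]] <- mortality[[nm]]
  if (n_years <= 0) stop("n_years must be positive")
  if (temp_d$ar1 < 0 || temp_d$ar1 >= 1 || rh_d$ar1 < 0 || rh_d$ar1 >= 1) {
    stop("ar1 coefficients must lie in [0, 1)")
  }
  if (mort_d$baseline <= 0) stop("baseline must be positive")
  if (mort_d$overdispersion < 1) stop("overdispersion must be >= 1")
  if (length(mort_d$dow_multipliers) != 7L) stop("dow_multipliers must have length 7")
  if (abs(sum(cats$share) - 1) > 1e-8) stop("category shares must sum to 1")
  if (!inherits(surface, "truth_surface")) stop("surface must be a truth_surface")
  structure(list(n_years = n_years, start = as.Date(start), temp = temp_d,
                 rh = rh_d, mortality = mort_d, surface = surface, cats = cats),
            class = "synth_config")
}

# AR(1) series with burn-in so the start is (approximately) stationary.
ar1_series <- function(n, ar1, sd_innov, burn = 200L) {
  e <- stats::rnorm(n + burn, 0, sd_innov)
  as.numeric(stats::filter(e, ar1, method = "recursive"))[(burn + 1L):(burn + n)]
}

#' Generate synthetic daily weather
#'
#' Temperature: seasonal sinusoid plus stationary AR(1) noise,
#' `mean + amplitude * sin(2 pi (doy - phase) / 365.25) + AR1`. Humidity is
#' generated analogously and clamped to (0, 100]. Fully reproducible from
#' the seed (substream `seed + 1`).
#'
#' @param config a `synth_config`.
#' @param seed integer seed.
#' @return data frame with `date`, `tmean`, `rh`.
#' @export
generate_weather <- function(config, seed) {
  set.seed(as.integer(seed) + 1L)
  n <- round(config$n_years * 365.25)
  dates <- seq(config$start, by = "day", length.out = n)
  doy <- as.POSIXlt(dates)$yday + 1
  seas <- function(p) sin(2 * pi * (doy - p$phase) / 365.25) * p$amplitude
  tmean <- config$temp$mean + seas(config$temp) +
    ar1_series(n, config$temp$ar1, config$temp$innovation_sd)
  rh <- config$rh$mean + seas(config$rh) +
    ar1_series(n, config$rh$ar1, config$rh$innovation_sd)
  rh <- pmin(100, pmax(30, rh))
  data.frame(date = dates, tmean = tmean, rh = rh)
}

#' Generate synthetic daily mortality counts
#'
#' Forward simulation of the mortality model: for category c on day t,
#' `log mu = log(share_c * baseline) + mult_c * s(t) * f_lagged(t)
#'  + log dow_mult + seasonal nuisance`, where `f_lagged` is the true
#' surface convolved with its lag profile (early days reuse the first
#' temperature as lag history) and `s(t)` the season multiplier. The
#' all-cause total is drawn from a gamma-Poisson mixture with variance
#' `omega * mu` (plain Poisson when omega = 1) and split multinomially
#' across categories with day-specific probabilities `mu_c / mu_total`, so
#' category counts sum to the total exactly. Substreams: counts use
#' `seed + 2`, the split `seed + 3`.
#'
#' @param weather output of [generate_weather()].
#' @param config a `synth_config`.
#' @param seed integer seed.
#' @return list with `data` (data frame `date`, `tmean`, `rh`, `all`, one
#'   column per category) and `truth` (per-day cumulative true log RR,
#'   expected counts, the surface).
#' @export
generate_mortality <- function(weather, config, seed) {
  surface <- config$surface
  n <- nrow(weather)
  L <- length(surface$lag_weights) - 1L
  if (n <= L) stop("weather series shorter than the lag profile support")
  g <- cumulative_truth(surface, weather$tmean)
  eff <- numeric(n)
  for (l in 0:L) {
    lagged <- c(rep(g[1L], l), g[seq_len(n - l)])
    eff <- eff + surface$lag_weights[l + 1L] * lagged
  }
  sn <- as.character(classify_season(weather$date))
  smult <- surface$season_multipliers[sn]
  doy <- as.POSIXlt(weather$date)$yday + 1
  mort <- config$mortality
  nuis <- mort$seasonal_amplitude *
    sin(2 * pi * (doy - mort$seasonal_phase) / 365.25)
  dowm <- mort$dow_multipliers[as.integer(format(weather$date, "%u"))]
  cats <- config$cats
  mu_cat <- sapply(seq_len(nrow(cats)), function(i) {
    cats$share[i] * mort$baseline *
      exp(cats$mult[i] * smult * eff + log(dowm) + nuis)
  })
  mu_tot <- rowSums(mu_cat)
  if (any(!is.finite(mu_tot)) || max(mu_tot) > 1e6) {
    stop("expected counts overflow; reduce the surface slopes")
  }
  set.seed(as.integer(seed) + 2L)
  omega <- mort$overdispersion
  lambda <- if (omega > 1) {
    stats::rgamma(n, shape = mu_tot / (omega - 1), scale = omega - 1)
  } else mu_tot
  y_tot <- stats::rpois(n, lambda)
  set.seed(as.integer(seed) + 3L)
  p <- mu_cat / mu_tot
  split <- t(vapply(seq_len(n), function(t) {
    drop(stats::rmultinom(1L, y_tot[t], p[t, ]))
  }, integer(nrow(cats))))
  colnames(split) <- cats$name
  data <- data.frame(date = weather$date, tmean = weather$tmean,
                     rh = weather$rh, all = y_tot, split,
                     check.names = FALSE)
  list(data = data,
       truth = list(surface = surface, cumulative_logrr = eff,
                    expected = mu_tot))
}

#' Simulate a full synthetic dataset
#'
#' Weather plus mortality, returned as a validated `mortality_ts` together
#' with the ground-truth bundle. Deterministic given `(config, seed)`.
#'
#' @param config a `synth_config`.
#' @param seed integer seed.
#' @return object of class `synth_dataset`: `series` (a `mortality_ts`
#'   with categories `all` plus the configured split), `truth`, `config`,
#'   `seed`.
#' @export
simulate_dataset <- function(config = synth_config(), seed = 1L) {
  weather <- generate_weather(config, seed)
  mort <- generate_mortality(weather, config, seed)
  dat <- mort$data
  catcols <- setdiff(names(dat), c("date", "tmean", "rh"))
  series <- mortality_ts(dat$date, dat$tmean, dat$rh,
                         dat[, catcols, drop = FALSE])
  structure(list(series = series, truth = mort$truth, config = config,
                 seed = as.integer(seed)),
            class = "synth_dataset")
}
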