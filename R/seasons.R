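#' Split a series into PAGASA season sub-series
#'
#' Partitions the rows by [classify_season()]. Each sub-series keeps the
#' original dates and row indices and gains two within-season clocks:
#' `doy_season` (day position inside the contiguous seasonal block, so DJF
#' blocks that wrap the year boundary count December and the following
#' January/February as one block) and `time_season` (sequential index over
#' all of that season's days across years, for the long-term trend).
#' Lagged exposures are **not** recomputed here: season blocks from
#' different years are not a continuous series, so cross-basis rows must be
#' built on the full series first and then subset.
#'
#' @param series a `mortality_ts`.
#' @return named list (`DJF`, `MAM`, `JJA`, `SON`) of data frames, each
#'   with the series columns plus `row`, `doy_season`, `time_season`.
#'   Seasons with fewer than 60 days are an error.
#' @export
split_by_season <- function(series) {
  sn <- classify_season(series$date)
  blocks <- cumsum(c(1L, as.integer(sn[-1L] != sn[-length(sn)])))
  doy_season <- stats::ave(seq_along(sn), blocks, FUN = seq_along)
  out <- list()
  for (s in levels(sn)) {
    rows <- which(sn == s)
    if (length(rows) < 60L) {
      stop("season ", s, " has only ", length(rows), " days (< 60); insufficient data")
    }
    sub <- as.data.frame(series)[rows, , drop = FALSE]
    sub$row <- rows
    sub$doy_season <- doy_season[rows]
    sub$time_season <- seq_along(rows)
    rownames(sub) <- NULL
    out[[s]] <- sub
  }
  out
}

#' Fit a season-specific log-mortality model
#'
#' Ordinary least squares of the log-transformed daily count,
#' `log(deaths + shift)` (shift 1 by default; 0.5 is the common
#' alternative), on the cross-basis block carried over from the full
#' continuous series, a within-season day-of-year NCS (4 df), a
#' within-season trend NCS (3 df), a humidity NCS (3 df), day-of-week
#' dummies and the holiday indicator. The Gaussian fit with classical
#' covariance is the stable choice when season-sliced counts leave a
#' quasi-Poisson fit with very wide intervals.
#'
#' @param sub one element of [split_by_season()].
#' @param cb a `crossbasis` built on the FULL series' temperatures (lags
#'   must cross season boundaries).
#' @param config options: `category` (default first category), `log_shift`
#'   (default 1), `holidays`.
#' @return object of class `season_fit`: coefficients, `vcov`, `sigma2`,
#'   `df_residual`, `cb_cols`, `season`, `n`, spec metadata.
#' @export
fit_season_model <- function(sub, cb, config = list()) {
  cfg <- pipeline_defaults(config)
  shift <- if (is.null(cfg$log_shift)) 1 else cfg$log_shift
  cat <- if (is.null(cfg$category)) setdiff(names(sub), c("date", "tmean", "rh", "row", "doy_season", "time_season"))[1L] else cfg$category
  keep <- sub$row %in% cb$usable_rows
  sub <- sub[keep, , drop = FALSE]
  idx <- match(sub$row, cb$usable_rows)
  doyb <- ncs_basis(sub$doy_season, default_knots(sub$doy_season, 4L))
  colnames(doyb) <- paste0("doy", 1:4)
  timeb <- ncs_basis(sub$time_season, default_knots(sub$time_season, 3L))
  colnames(timeb) <- paste0("time", 1:3)
  rhb <- ncs_basis(sub$rh, default_knots(sub$rh, 3L))
  colnames(rhb) <- paste0("rh", 1:3)
  dw <- droplevels(factor(as.integer(format(sub$date, "%u")) - 1L, levels = 0:6))
  dowb <- if (nlevels(dw) > 1L) {
    m <- stats::model.matrix(~dw)[, -1L, drop = FALSE]
    colnames(m) <- sub("^dw", "dow", colnames(m))
    m
  } else NULL
  hod <- as.integer(sub$date %in% as.Date(cfg$holidays))
  hodb <- if (length(unique(hod)) > 1L) matrix(hod, ncol = 1L, dimnames = list(NULL, "hod")) else NULL
  X <- cbind("(Intercept)" = 1, cb$matrix[idx, , drop = FALSE],
             doyb, timeb, rhb, dowb, hodb)
  y <- log(sub[[cat]] + shift)
  fit <- stats::lm.fit(X, y)
  p <- fit$rank
  if (p < ncol(X)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    stop("season design is rank deficient; aliased column(s): ",
         paste(bad, collapse = ", "))
  }
  df_res <- length(y) - p
  sigma2 <- sum(fit$residuals^2) / df_res
  cov_u <- chol2inv(chol(crossprod(X)))
  dimnames(cov_u) <- list(colnames(X), colnames(X))
  structure(list(coefficients = fit$coefficients, vcov = sigma2 * cov_u,
                 sigma2 = sigma2, df_residual = df_res,
                 cb_cols = 1L + seq_len(ncol(cb$matrix)),
                 season = as.character(classify_season(sub$date[1L])),
                 n = length(y), category = cat, log_shift = shift,
                 pred_spec = cb$pred_spec, lag_spec = cb$lag_spec,
                 max_lag = cb$max_lag),
            class = "season_fit")
}

#' Season-specific exposure-response curve
#'
#' Contrast-based effect curve on the log-count scale, exponentiated and
#' centered at `ref` -- an RR-analogue, since the response is a log count
#' rather than a rate. CIs are delta-method Wald with the Gaussian
#' covariance.
#'
#' @param fit a `season_fit`.
#' @param grid temperatures (default 0.1 degree grid over the basis range).
#' @param ref reference temperature.
#' @return an `exposure_curve`.
#' @export
season_rr <- function(fit, grid = NULL, ref) {
  predict_curve(fit, list(pred_spec = fit$pred_spec, lag_spec = fit$lag_spec,
                          max_lag = fit$max_lag), grid = grid, ref = ref)
}

#' Per-degree season slope between two temperatures
#'
#' Cumulative log-RR-analogue contrast between `t_hi` and `t_lo` divided by
#' the temperature difference, with delta-method SE -- the "temperature
#' slope" summary reported per season.
#'
#' @param fit a `season_fit` (or `qp_fit`).
#' @param t_lo,t_hi temperatures with `t_lo < t_hi`.
#' @return one-row data frame: `slope`, `se`, `ci_low`, `ci_high`,
#'   `rr_per_deg` (exponentiated slope with its CI columns
#'   `rr_ci_low`/`rr_ci_high`).
#' @export
season_slope <- function(fit, t_lo, t_hi) {
  stopifnot(t_lo < t_hi)
  v <- crossbasis_contrast(fit$pred_spec, fit$lag_spec, fit$max_lag,
                           t_hi, t_lo) / (t_hi - t_lo)
  beta <- fit$coefficients[fit$cb_cols]
  V <- fit$vcov[fit$cb_cols, fit$cb_cols, drop = FALSE]
  est <- sum(v * beta)
  se <- sqrt(max(0, drop(v %*% V %*% v)))
  data.frame(slope = est, se = se, ci_low = est - 1.96 * se,
             ci_high = est + 1.96 * se, rr_per_deg = exp(est),
             rr_ci_low = exp(est - 1.96 * se), rr_ci_high = exp(est + 1.96 * se))
}

#' Season-stratified analysis
#'
#' Builds the cross-basis once on the full continuous series, splits the
#' rows by PAGASA season, fits the season-specific log-mortality model in
#' each, and summarizes each season's heat slope (between configurable
#' anchor temperatures, by default the season's 75th and 99th percentile
#' temperatures) plus the full effect curve.
#'
#' @param series a `mortality_ts`.
#' @param config pipeline options as elsewhere, plus `season_pred`
#'   (`"ncs"` default, `"linear"`, or `"sthr"` with
#'   `season_threshold`), `slope_anchors` (percentiles, default
#'   `c(75, 99)`).
#' @return object of class `season_analysis`: `fits`, `curves`, `table`
#'   (season, n, slope, se, CI, RR per degree).
#' @export
run_season_analysis <- function(series, config = list()) {
  cfg <- pipeline_defaults(config)
  if (is.null(cfg$season_pred)) cfg$season_pred <- "ncs"
  if (is.null(cfg$slope_anchors)) cfg$slope_anchors <- c(75, 99)
  pred_spec <- switch(cfg$season_pred,
    ncs = default_knots(series$tmean, cfg$pred_df),
    linear = basis_spec("linear"),
    sthr = basis_spec("sthr", thresholds = list(high = cfg$season_threshold)),
    stop("unknown season_pred: ", cfg$season_pred)
  )
  lag_spec <- lag_knots(cfg$max_lag, cfg$lag_df)
  cb <- build_crossbasis(series$tmean, pred_spec, lag_spec, cfg$max_lag)
  subs <- split_by_season(series)
  fits <- list()
  curves <- list()
  tab <- NULL
  for (s in names(subs)) {
    fit <- fit_season_model(subs[[s]], cb, cfg)
    tm <- subs[[s]]$tmean
    anchors <- if (cfg$season_pred == "sthr") {
      c(cfg$season_threshold, cfg$season_threshold + 1)
    } else {
      stats::quantile(tm, cfg$slope_anchors / 100, type = 7, names = FALSE)
    }
    sl <- season_slope(fit, anchors[1L], anchors[2L])
    ref <- stats::median(tm)
    grid <- seq(min(tm), max(tm), by = 0.1)
    curves[[s]] <- season_rr(fit, grid = grid, ref = ref)
    fits[[s]] <- fit
    tab <- rbind(tab, cbind(season = s, n = fit$n, sl))
  }
  rownames(tab) <- NULL
  structure(list(fits = fits, curves = curves, table = tab, config = cfg),
            class = "season_analysis")
}

#' @export
print.season_analysis <- function(x, ...) {
  cat("Season-specific temperature-mortality analysis (log-count OLS)\n")
  print(x$table, digits = 3)
  invisible(x)
}
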