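#' Exposure-response curve from a fitted model
#'
#' Computes the log relative risk of each grid temperature versus `ref` by
#' contracting cross-basis contrasts with the fitted cross-basis
#' coefficients; pointwise standard errors come from the delta method,
#' `se(x) = sqrt(c(x)' V c(x))` with `V` the dispersion-scaled coefficient
#' covariance; 95% intervals are Wald on the log scale
#' (`exp(log_rr +/- 1.96 se)`).
#'
#' @param fit a `qp_fit` (or `season_fit`) with `cb_cols` set.
#' @param cb_meta a `crossbasis` object or a list with `pred_spec`,
#'   `lag_spec`, `max_lag` matching the fit.
#' @param grid temperatures to evaluate (default: 0.1 degree C grid over the
#'   predictor basis boundary, or the threshold region +/- 5 for threshold
#'   bases).
#' @param ref reference temperature (RR = 1 there exactly).
#' @param mode `"cumulative"` (sum over the lag window) or `"lag_specific"`.
#' @param lag lag day for `lag_specific` mode.
#' @return object of class `exposure_curve`: list with `grid`, `log_rr`,
#'   `se`, `rr`, `ci_low`, `ci_high`, `ref`, `mmt` (NA until
#'   [find_mmt()] is run), `mode`, `lag`, and the spec metadata. Grid points
#'   outside the predictor boundary are flagged in `extrapolated` with a
#'   warning.
#' @export
predict_curve <- function(fit, cb_meta, grid = NULL, ref,
                          mode = c("cumulative", "lag_specific"), lag = NULL) {
  mode <- match.arg(mode)
  if (is.null(fit$cb_cols)) stop("fit carries no cross-basis column index")
  pred_spec <- cb_meta$pred_spec
  lag_spec <- cb_meta$lag_spec
  max_lag <- cb_meta$max_lag
  if (is.null(grid)) {
    rng <- if (pred_spec$kind == "ncs") pred_spec$boundary else {
      th <- unlist(pred_spec$thresholds)
      c(min(th) - 5, max(th) + 5)
    }
    grid <- seq(rng[1L], rng[2L], by = 0.1)
  }
  extrapolated <- rep(FALSE, length(grid))
  if (pred_spec$kind == "ncs") {
    extrapolated <- grid < pred_spec$boundary[1L] | grid > pred_spec$boundary[2L]
    if (any(extrapolated)) {
      warning(sum(extrapolated), " grid point(s) outside the basis boundary (extrapolation)")
    }
  }
  M <- contrast_matrix(pred_spec, lag_spec, max_lag, grid, ref, mode, lag)
  beta <- fit$coefficients[fit$cb_cols]
  V <- fit$vcov[fit$cb_cols, fit$cb_cols, drop = FALSE]
  log_rr <- drop(M %*% beta)
  se <- sqrt(pmax(0, rowSums((M %*% V) * M)))
  structure(list(grid = grid, log_rr = log_rr, se = se,
                 rr = exp(log_rr),
                 ci_low = exp(log_rr - 1.96 * se),
                 ci_high = exp(log_rr + 1.96 * se),
                 ref = ref, mmt = NA_real_, mode = mode, lag = lag,
                 pred_spec = pred_spec, lag_spec = lag_spec,
                 max_lag = max_lag, extrapolated = extrapolated),
            class = "exposure_curve")
}

#' Minimum mortality temperature of a curve
#'
#' Grid argmin of the log RR within a search window; ties are broken toward
#' the lowest temperature. The default window passed by the pipeline is the
#' 10th-90th percentile range of the observed temperatures, because spline
#' tails are variance-inflated and an interior MMT is the quantity of
#' epidemiological interest.
#'
#' @param curve an `exposure_curve`.
#' @param window length-2 temperature bounds (default: the whole grid).
#' @return the MMT in degrees C. A flat curve returns the window midpoint
#'   with a warning.
#' @export
find_mmt <- function(curve, window = range(curve$grid)) {
  keep <- curve$grid >= window[1L] & curve$grid <= window[2L]
  if (!any(keep)) stop("search window contains no grid points")
  g <- curve$grid[keep]
  y <- curve$log_rr[keep]
  if (max(y) - min(y) < 1e-12) {
    warning("curve is flat over the search window; returning its midpoint")
    return(mean(range(g)))
  }
  g[which.min(y)]
}

#' Relative risks at temperature percentiles
#'
#' Evaluates a (typically MMT-centered) curve at the 1st/5th/95th/99th
#' percentile temperatures of the analyzed series, interpolating log RR and
#' its SE linearly between grid points. Percentiles use the type-7 rule.
#' If a percentile temperature falls outside the curve's grid and `fit` is
#' supplied, the grid is extended and the curve recomputed; otherwise this
#' is an error.
#'
#' @param curve an `exposure_curve`.
#' @param x the temperature series the percentiles refer to.
#' @param percentiles percentile levels (default `c(1, 5, 95, 99)`).
#' @param fit optional fit for grid extension.
#' @return data frame with `percentile`, `temperature`, `rr`, `ci_low`,
#'   `ci_high`.
#' @export
rr_at_percentiles <- function(curve, x, percentiles = c(1, 5, 95, 99),
                              fit = NULL) {
  temps <- stats::quantile(x, percentiles / 100, type = 7, names = FALSE)
  rng <- range(curve$grid)
  if (any(temps < rng[1L] | temps > rng[2L])) {
    if (is.null(fit)) stop("percentile temperature outside the curve grid")
    grid <- seq(min(rng[1L], temps), max(rng[2L], temps), by = 0.1)
    curve <- predict_curve(fit, curve, grid = grid, ref = curve$ref,
                           mode = curve$mode, lag = curve$lag)
  }
  lr <- stats::approx(curve$grid, curve$log_rr, xout = temps)$y
  se <- stats::approx(curve$grid, curve$se, xout = temps)$y
  data.frame(percentile = percentiles, temperature = temps,
             rr = exp(lr), ci_low = exp(lr - 1.96 * se),
             ci_high = exp(lr + 1.96 * se))
}

#' Category-stratified exposure-response analysis
#'
#' Runs the full pipeline -- cross-basis, quasi-Poisson fit, MMT search,
#' MMT-centered percentile RRs -- independently for each mortality category
#' against the shared temperature series, and assembles a percentile RR
#' table (one row block per category, one MMT per category).
#'
#' @param series a `mortality_ts`.
#' @param cats categories to analyze (default: all in the series).
#' @param config list of options: `pred_df` (default 4), `lag_df` (2),
#'   `max_lag` (13), `trend_df_per_year` (7), `rh_df` (3), `percentiles`
#'   (`c(1, 5, 95, 99)`), `mmt_window` (percentile bounds, `c(10, 90)`),
#'   `holidays` (dates, default none).
#' @return object of class `rr_analysis`: list with `table` (the percentile
#'   RR table), `curves` (MMT-centered `exposure_curve` per category),
#'   `fits`, `mmt` (named vector), `config`.
#' @export
run_category_analysis <- function(series, cats = NULL, config = list()) {
  if (is.null(cats)) cats <- categories(series)
  if (length(cats) == 0L) stop("empty category list")
  cfg <- pipeline_defaults(config)
  cov <- derive_calendar_covariates(series, cfg$holidays)
  pred_spec <- default_knots(series$tmean, cfg$pred_df)
  lag_spec <- lag_knots(cfg$max_lag, cfg$lag_df)
  cb <- build_crossbasis(series$tmean, pred_spec, lag_spec, cfg$max_lag)
  des <- assemble_design(series, cb, cov, cfg)
  mmt_window <- stats::quantile(series$tmean, cfg$mmt_window / 100,
                                type = 7, names = FALSE)
  ref0 <- stats::median(series$tmean)
  tab <- NULL
  curves <- list()
  fits <- list()
  mmts <- c()
  for (cat in cats) {
    y <- series[[cat]][des$usable]
    if (all(y == 0)) {
      warning("category '", cat, "' has all-zero counts; skipped")
      next
    }
    fit <- fit_quasipoisson(y, des$X, cb_cols = des$cb_cols, design_meta = des$meta)
    curve0 <- predict_curve(fit, cb, ref = ref0)
    mmt <- find_mmt(curve0, mmt_window)
    curve <- predict_curve(fit, cb, ref = mmt)
    curve$mmt <- mmt
    rows <- rr_at_percentiles(curve, series$tmean, cfg$percentiles, fit = fit)
    rows <- cbind(category = cat, rows, mmt = mmt)
    tab <- rbind(tab, rows)
    curves[[cat]] <- curve
    fits[[cat]] <- fit
    mmts[cat] <- mmt
  }
  if (is.null(tab)) stop("no analyzable categories")
  rownames(tab) <- NULL
  structure(list(table = tab, curves = curves, fits = fits, mmt = mmts,
                 cb = cb, config = cfg),
            class = "rr_analysis")
}

# Shared pipeline option defaults.
pipeline_defaults <- function(config = list()) {
  defaults <- list(pred_df = 4L, lag_df = 2L, max_lag = 13L,
                   trend_df_per_year = 7, rh_df = 3L,
                   percentiles = c(1, 5, 95, 99), mmt_window = c(10, 90),
                   holidays = as.Date(character()))
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  defaults
}

#' @export
print.rr_analysis <- function(x, ...) {
  cat("Category-stratified temperature-mortality analysis\n")
  cat("  max lag:", x$cb$max_lag, "days; categories:",
      paste(names(x$curves), collapse = ", "), "\n")
  print(x$table, digits = 3)
  invisible(x)
}
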