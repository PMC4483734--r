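#' Threshold specification
#'
#' @param low optional low (cold-arm) threshold, degrees C.
#' @param high optional high (heat-arm) threshold, degrees C.
#' @param source how the thresholds were obtained: `"minima_of_ncs"`,
#'   `"grid_search"` or `"user"`.
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(low = NULL, high = NULL,
                           source = c("user", "minima_of_ncs", "grid_search")) {
  source <- match.arg(source)
  if (is.null(low) && is.null(high)) stop("at least one threshold is required")
  if (!is.null(low) && !is.null(high) && !(low < high)) stop("low must be < high")
  structure(list(low = low, high = high, source = source),
            class = "threshold_spec")
}

#' Interior local minima of an exposure-response curve
#'
#' Detects local minima of the log RR on the (uniform) grid by sign change
#' of the first differences; plateaus collapse to their lowest-temperature
#' point. Monotone curves yield an empty result. The returned temperatures
#' are ordered ascending and are the natural threshold candidates for the
#' double-threshold stage.
#'
#' @param curve an `exposure_curve`.
#' @return numeric vector of minimum temperatures (possibly empty).
#' @export
locate_minima <- function(curve) {
  y <- curve$log_rr
  g <- curve$grid
  r <- rle(y)
  ry <- r$values
  rstart <- cumsum(c(1L, utils::head(r$lengths, -1L)))
  m <- length(ry)
  if (m < 3L) return(numeric(0))
  out <- numeric(0)
  for (i in 2:(m - 1L)) {
    if (ry[i] < ry[i - 1L] && ry[i] < ry[i + 1L]) out <- c(out, g[rstart[i]])
  }
  sort(out)
}

#' Fit a threshold (hockey-stick) mortality model
#'
#' Replaces the predictor spline with a single-high-threshold or
#' double-threshold basis while keeping the lag spline and all covariate
#' controls, refits the quasi-Poisson regression, and returns the fit
#' together with the exposure-response curve centered inside the null
#' region (so RR = 1 there by construction). Also reports the per-degree
#' log-RR slope of each arm with its SE: for the heat arm the cumulative
#' contrast of `high + 1` versus `high`, for the cold arm `low - 1` versus
#' `low`.
#'
#' @param series a `mortality_ts`.
#' @param thresholds a `threshold_spec` within the observed temperature
#'   range.
#' @param config pipeline options as in [run_category_analysis()]; the
#'   modelled category defaults to `config$category` or the first category.
#' @return list with `fit`, `curve`, `spec` (the predictor `basis_spec`),
#'   `slopes` (data frame arm/slope/se/ci), `thresholds`.
#' @export
fit_threshold_model <- function(series, thresholds, config = list()) {
  cfg <- pipeline_defaults(config)
  cat <- if (is.null(cfg$category)) categories(series)[1L] else cfg$category
  rng <- range(series$tmean)
  for (th in c(thresholds$low, thresholds$high)) {
    if (th < rng[1L] || th > rng[2L]) {
      stop("threshold ", th, " outside the observed temperature range [",
           rng[1L], ", ", rng[2L], "]")
    }
  }
  pred_spec <- if (is.null(thresholds$low)) {
    basis_spec("sthr", thresholds = list(high = thresholds$high))
  } else if (is.null(thresholds$high)) {
    # single low threshold: cold arm only, realized as a dthr with the heat
    # arm pinned at the data maximum (contributes nothing)
    basis_spec("dthr", thresholds = list(low = thresholds$low, high = rng[2L]))
  } else {
    basis_spec("dthr", thresholds = thresholds[c("low", "high")])
  }
  lag_spec <- lag_knots(cfg$max_lag, cfg$lag_df)
  cov <- derive_calendar_covariates(series, cfg$holidays)
  cb <- build_crossbasis(series$tmean, pred_spec, lag_spec, cfg$max_lag)
  des <- assemble_design(series, cb, cov, cfg)
  y <- series[[cat]][des$usable]
  fit <- fit_quasipoisson(y, des$X, cb_cols = des$cb_cols, design_meta = des$meta)
  ref <- if (is.null(thresholds$high)) thresholds$low else thresholds$high
  grid <- seq(rng[1L], rng[2L], by = 0.1)
  curve <- predict_curve(fit, cb, grid = grid, ref = ref)
  slopes <- threshold_slopes(fit, cb, thresholds)
  list(fit = fit, curve = curve, spec = pred_spec, slopes = slopes,
       thresholds = thresholds)
}

# Per-degree cumulative log-RR slope of each threshold arm, delta-method SE.
threshold_slopes <- function(fit, cb_meta, thresholds) {
  beta <- fit$coefficients[fit$cb_cols]
  V <- fit$vcov[fit$cb_cols, fit$cb_cols, drop = FALSE]
  one <- function(temp, ref, arm) {
    v <- crossbasis_contrast(cb_meta$pred_spec, cb_meta$lag_spec,
                             cb_meta$max_lag, temp, ref)
    est <- sum(v * beta)
    se <- sqrt(max(0, drop(v %*% V %*% v)))
    data.frame(arm = arm, slope = est, se = se,
               ci_low = est - 1.96 * se, ci_high = est + 1.96 * se)
  }
  out <- NULL
  if (!is.null(thresholds$high)) {
    out <- rbind(out, one(thresholds$high + 1, thresholds$high, "heat"))
  }
  if (!is.null(thresholds$low)) {
    out <- rbind(out, one(thresholds$low - 1, thresholds$low, "cold"))
  }
  rownames(out) <- NULL
  out
}

#' Grid search over threshold candidates
#'
#' Evaluates single-high-threshold fits over `candidate_highs` and (when
#' `candidate_lows` is non-empty) double-threshold fits over every
#' `low < high` pair, scoring each by QAIC (with the dispersion of a rich
#' NCS-NCS reference fit) or by deviance explained. Selection follows the
#' principle of minimizing the low-temperature effect: among candidates
#' within a near-optimality band of the best criterion value (2 QAIC units,
#' or 0.005 deviance-explained), the model whose cold-arm slope is closest
#' to null is chosen -- an STHR model, having no cold arm, wins whenever it
#' is competitive, which is exactly the collapse from a double to a single
#' high threshold.
#'
#' @param series a `mortality_ts`.
#' @param candidate_lows cold-threshold candidates (degrees C), or
#'   `NULL`/empty for an STHR-only search.
#' @param candidate_highs heat-threshold candidates (degrees C).
#' @param criterion `"qaic"` (default) or `"deviance_explained"`.
#' @param config pipeline options; `config$phi_ref` overrides the reference
#'   dispersion.
#' @return list with `spec` (selected `threshold_spec`, source
#'   `"grid_search"`), `best` (the refitted selected model, as from
#'   [fit_threshold_model()]), `trace` (one row per candidate with
#'   criterion values and cold-arm z), `criterion`.
#' @export
threshold_grid_search <- function(series, candidate_lows = NULL, candidate_highs,
                                  criterion = c("qaic", "deviance_explained"),
                                  config = list()) {
  criterion <- match.arg(criterion)
  cfg <- pipeline_defaults(config)
  if (length(candidate_highs) == 0L) stop("empty candidate grid")
  cat <- if (is.null(cfg$category)) categories(series)[1L] else cfg$category
  cov <- derive_calendar_covariates(series, cfg$holidays)
  lag_spec <- lag_knots(cfg$max_lag, cfg$lag_df)

  phi_ref <- cfg$phi_ref
  if (is.null(phi_ref)) {
    ncs_cb <- build_crossbasis(series$tmean, default_knots(series$tmean, cfg$pred_df),
                               lag_spec, cfg$max_lag)
    ncs_des <- assemble_design(series, ncs_cb, cov, cfg)
    ncs_fit <- fit_quasipoisson(series[[cat]][ncs_des$usable], ncs_des$X,
                                cb_cols = ncs_des$cb_cols)
    phi_ref <- ncs_fit$dispersion
  }

  # fixed covariate block is identical across candidates; rebuild cheaply
  eval_cand <- function(low, high) {
    spec <- if (is.na(low)) basis_spec("sthr", thresholds = list(high = high)) else
      basis_spec("dthr", thresholds = list(low = low, high = high))
    cb <- build_crossbasis(series$tmean, spec, lag_spec, cfg$max_lag)
    des <- assemble_design(series, cb, cov, cfg)
    fit <- fit_quasipoisson(series[[cat]][des$usable], des$X, cb_cols = des$cb_cols)
    sl <- threshold_slopes(fit, cb, list(low = if (is.na(low)) NULL else low,
                                         high = high))
    cold <- sl[sl$arm == "cold", ]
    data.frame(low = low, high = high,
               qaic = qaic(fit, phi_ref),
               dev_expl = deviance_explained(fit),
               cold_slope = if (nrow(cold)) cold$slope else 0,
               cold_z = if (nrow(cold)) cold$slope / max(cold$se, 1e-12) else 0)
  }
  cand <- data.frame(low = NA_real_, high = candidate_highs)
  if (length(candidate_lows)) {
    pairs <- expand.grid(low = candidate_lows, high = candidate_highs)
    pairs <- pairs[pairs$low < pairs$high, ]
    cand <- rbind(cand, pairs)
  }
  trace <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    eval_cand(cand$low[i], cand$high[i])
  }))
  crit <- if (criterion == "qaic") trace$qaic else -trace$dev_expl
  band <- if (criterion == "qaic") 2 else 0.005
  near <- which(crit <= min(crit) + band)
  pick <- near[order(abs(trace$cold_z[near]), is.na(trace$low[near]) == FALSE,
                     crit[near])][1L]
  trace$selected <- seq_len(nrow(trace)) == pick
  spec <- threshold_spec(low = if (is.na(trace$low[pick])) NULL else trace$low[pick],
                         high = trace$high[pick], source = "grid_search")
  best <- fit_threshold_model(series, spec, cfg)
  list(spec = spec, best = best, trace = trace, criterion = criterion,
       phi_ref = phi_ref)
}

#' Run the three-stage model simplification
#'
#' Reproduces the objective model-transition procedure for one mortality
#' category:
#' \enumerate{
#'   \item fit the flexible NCS-NCS DLNM and compute its cumulative
#'     exposure-response curve and MMT;
#'   \item place thresholds at the curve's interior local minima -- a
#'     double-threshold (DTHR-NCS) model when two or more minima exist,
#'     otherwise a single high threshold at the MMT;
#'   \item grid-search thresholds around the stage-2 values (0.1 degree
#'     steps, clipped to the 1st-99th percentile range) and select by the
#'     near-optimality / minimal-cold-arm rule of
#'     [threshold_grid_search()], which collapses to STHR-NCS when the cold
#'     arm is negligible.
#' }
#' All stages share the same `max_lag`, hence identical usable rows, so
#' QAIC (referenced to the stage-1 dispersion) and deviance explained are
#' comparable across stages.
#'
#' @param series a `mortality_ts`.
#' @param config pipeline options as in [run_category_analysis()], plus
#'   `search_halfwidth` (degrees C around stage-2 thresholds, default 1).
#' @return object of class `transition_report`: `stages` (named list with
#'   per-stage thresholds, criteria, curve, slopes), `selected` (label of
#'   the final model), `trace` (stage-3 search trace),
#'   `criterion_equivalent` (TRUE when all stages sit within 2 QAIC).
#' @export
run_transition <- function(series, config = list()) {
  cfg <- pipeline_defaults(config)
  if (is.null(cfg$search_halfwidth)) cfg$search_halfwidth <- 1
  cat <- if (is.null(cfg$category)) categories(series)[1L] else cfg$category
  cfg$category <- cat
  cov <- derive_calendar_covariates(series, cfg$holidays)
  pred_spec <- default_knots(series$tmean, cfg$pred_df)
  lag_spec <- lag_knots(cfg$max_lag, cfg$lag_df)
  cb <- build_crossbasis(series$tmean, pred_spec, lag_spec, cfg$max_lag)
  des <- assemble_design(series, cb, cov, cfg)
  y <- series[[cat]][des$usable]
  fit1 <- fit_quasipoisson(y, des$X, cb_cols = des$cb_cols, design_meta = des$meta)
  phi_ref <- fit1$dispersion
  p <- stats::quantile(series$tmean, c(.01, .10, .90, .99), type = 7, names = FALSE)
  grid <- seq(min(series$tmean), max(series$tmean), by = 0.1)
  curve0 <- predict_curve(fit1, cb, grid = grid, ref = stats::median(series$tmean))
  mmt <- find_mmt(curve0, c(p[2L], p[3L]))
  curve1 <- predict_curve(fit1, cb, grid = grid, ref = mmt)
  curve1$mmt <- mmt

  minima <- locate_minima(curve1)
  minima <- minima[minima >= p[1L] & minima <= p[4L]]
  th2 <- if (length(minima) >= 2L) {
    threshold_spec(low = min(minima), high = max(minima), source = "minima_of_ncs")
  } else {
    threshold_spec(high = if (length(minima) == 1L) minima else mmt,
                   source = "minima_of_ncs")
  }
  stage2 <- fit_threshold_model(series, th2, cfg)

  clip <- function(g) g[g >= p[1L] & g <= p[4L]]
  hw <- cfg$search_halfwidth
  highs <- clip(seq(th2$high - hw, th2$high + hw, by = 0.1))
  lows <- if (is.null(th2$low)) NULL else clip(seq(th2$low - hw, th2$low + hw, by = 0.1))
  cfg$phi_ref <- phi_ref
  search <- threshold_grid_search(series, lows, highs,
                                  criterion = if (is.null(cfg$criterion)) "qaic" else cfg$criterion,
                                  config = cfg)
  stage3 <- search$best

  stage_stats <- function(fit) {
    c(qaic = qaic(fit, phi_ref), dev_expl = deviance_explained(fit),
      dispersion = fit$dispersion)
  }
  stages <- list(list(thresholds = NULL, mmt = mmt, curve = curve1,
                      stats = stage_stats(fit1), fit = fit1),
                 list(thresholds = th2, curve = stage2$curve,
                      slopes = stage2$slopes, stats = stage_stats(stage2$fit),
                      fit = stage2$fit),
                 list(thresholds = search$spec, curve = stage3$curve,
                      slopes = stage3$slopes, stats = stage_stats(stage3$fit),
                      fit = stage3$fit))
  names(stages) <- c("NCS-NCS",
                     if (is.null(th2$low)) "STHR-NCS (minima)" else "DTHR-NCS",
                     if (is.null(search$spec$low)) "STHR-NCS (searched)" else "DTHR-NCS (searched)")
  qaics <- vapply(stages, function(s) s$stats[["qaic"]], numeric(1))
  structure(list(stages = stages, selected = names(stages)[3L],
                 trace = search$trace,
                 criterion_equivalent = diff(range(qaics)) <= 2,
                 usable_rows = des$usable, config = cfg),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat("Model-simplification transition report\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    th <- s$thresholds
    cat(sprintf("  %-18s QAIC %9.2f  dev.expl %5.3f  %s\n", nm,
                s$stats[["qaic"]], s$stats[["dev_expl"]],
                if (is.null(th)) sprintf("MMT %.1f", s$mmt)
                else paste0("thresholds [", paste(unlist(th[c("low", "high")]),
                                                  collapse = ", "), "]")))
  }
  cat("  selected:", x$selected,
      if (x$criterion_equivalent) "(stages criterion-equivalent within 2 QAIC)" else "", "\n")
  invisible(x)
}
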