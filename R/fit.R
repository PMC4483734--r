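#' Assemble the mortality regression design
#'
#' Builds the full quasi-Poisson design on the cross-basis' usable rows:
#' intercept | cross-basis block | long-term trend NCS on the time index
#' (7 df per year of data by default, the conventional seasonal-control
#' density for daily mortality series) | humidity NCS (3 df) | day-of-week
#' dummies | holiday indicator. Zero-variance blocks (constant humidity, a
#' holiday indicator that never fires) are dropped -- humidity with a
#' warning. Rank deficiency is an error naming the collinear columns.
#'
#' @param series a `mortality_ts`.
#' @param cb a `crossbasis` built on `series$tmean`.
#' @param covariates output of [derive_calendar_covariates()] for `series`.
#' @param config list; honoured entries `trend_df_per_year` (default 7) and
#'   `rh_df` (default 3).
#' @return list with `X` (design matrix), `usable` (row indices into the
#'   series), `cb_cols` (column indices of the cross-basis block), and
#'   `meta` (per-block column names).
#' @export
assemble_design <- function(series, cb, covariates, config = list()) {
  trend_per_year <- if (is.null(config$trend_df_per_year)) 7 else config$trend_df_per_year
  rh_df <- if (is.null(config$rh_df)) 3L else as.integer(config$rh_df)
  usable <- cb$usable_rows
  n_years <- nrow(series) / 365.25
  trend_df <- max(3L, as.integer(round(trend_per_year * n_years)))

  ti <- covariates$time_index[usable]
  trend <- ncs_basis(ti, default_knots(ti, trend_df))
  colnames(trend) <- paste0("trend", seq_len(ncol(trend)))

  rh <- series$rh[usable]
  if (stats::sd(rh) == 0) {
    warning("humidity is constant; humidity spline dropped")
    rhb <- NULL
  } else {
    rhb <- ncs_basis(rh, default_knots(rh, rh_df))
    colnames(rhb) <- paste0("rh", seq_len(ncol(rhb)))
  }

  dw <- droplevels(covariates$dow[usable])
  dowb <- if (nlevels(dw) > 1L) {
    m <- stats::model.matrix(~dw)[, -1L, drop = FALSE]
    colnames(m) <- sub("^dw", "dow", colnames(m))
    m
  } else NULL

  hod <- covariates$hod[usable]
  hodb <- if (length(unique(hod)) > 1L) matrix(hod, ncol = 1L, dimnames = list(NULL, "hod")) else NULL

  X <- cbind("(Intercept)" = 1, cb$matrix, trend, rhb, dowb, hodb)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(X = X, usable = usable,
       cb_cols = 1L + seq_len(ncol(cb$matrix)),
       meta = list(trend_df = trend_df, rh_df = if (is.null(rhb)) 0L else rh_df,
                   colnames = colnames(X)))
}

#' Fit a quasi-Poisson regression
#'
#' Log-link Poisson mean structure fitted by iteratively reweighted least
#' squares (relative deviance tolerance 1e-9, at most 50 iterations), with
#' the dispersion estimated from the Pearson statistic,
#' `phi = sum((y - mu)^2 / mu) / df_residual`, and the coefficient
#' covariance scaled as `phi * (X' W X)^-1`. The mean structure also accepts
#' non-integer non-negative responses (used by deterministic zero-noise
#' checks).
#'
#' @param y non-negative response counts, one per design row.
#' @param X full-column-rank design matrix (including the intercept).
#' @param cb_cols optional column indices of the cross-basis block; stored
#'   for downstream effect estimation.
#' @param design_meta optional metadata list stored verbatim.
#' @return An object of class `qp_fit`: coefficients, `vcov` (dispersion-
#'   scaled), `dispersion`, `deviance`, `null_deviance`, `df_residual`,
#'   `rank`, `fitted`, `y`, `qll` (Poisson log-likelihood at the fit),
#'   `cb_cols`, `design_meta`.
#' @export
fit_quasipoisson <- function(y, X, cb_cols = NULL, design_meta = NULL) {
  if (any(!is.finite(y)) || any(y < 0)) stop("y must be finite and non-negative")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  fit <- stats::glm.fit(X, y, family = stats::quasipoisson(link = "log"),
                        control = stats::glm.control(epsilon = 1e-9, maxit = 50),
                        intercept = "(Intercept)" %in% colnames(X))
  if (!fit$converged) {
    stop("IRLS did not converge in 50 iterations (deviance ",
         format(fit$deviance), ")")
  }
  p <- fit$rank
  if (p < ncol(X)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(bad, collapse = ", "))
  }
  mu <- fit$fitted.values
  if (any(mu < 1e-10) || any(mu > 1e10)) {
    stop("fitted means are collapsing to 0 or diverging; possible separation")
  }
  df_res <- length(y) - p
  if (df_res <= 0L) stop("no residual degrees of freedom")
  phi <- sum((y - mu)^2 / mu) / df_res
  w <- fit$weights
  cov_u <- chol2inv(chol(crossprod(X * sqrt(w))))
  dimnames(cov_u) <- list(colnames(X), colnames(X))
  qll <- sum(ifelse(y > 0, y * log(mu), 0) - mu - lgamma(y + 1))
  structure(list(coefficients = fit$coefficients,
                 vcov = phi * cov_u,
                 dispersion = phi,
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 df_residual = df_res,
                 rank = p,
                 fitted = mu,
                 y = y,
                 qll = qll,
                 cb_cols = cb_cols,
                 design_meta = design_meta),
            class = "qp_fit")
}

#' Fraction of deviance explained
#'
#' `1 - deviance / null_deviance` for any fit carrying both deviances --
#' the quasi-Poisson analogue of R-squared used to report how much of the
#' daily mortality variability the model accounts for.
#'
#' @param fit a `qp_fit` (or any list with `deviance` and `null_deviance`).
#' @return fraction in \[0, 1\].
#' @export
deviance_explained <- function(fit) {
  if (is.null(fit$null_deviance) || fit$null_deviance <= .Machine$double.eps) {
    stop("null deviance is zero (constant response); deviance explained undefined")
  }
  1 - fit$deviance / fit$null_deviance
}

#' Quasi-AIC for model comparison under overdispersion
#'
#' `-2 * loglik / phi_reference + 2 * rank`, with the Poisson log-likelihood
#' evaluated at the quasi-Poisson fit and a dispersion taken from the richest
#' model under comparison (so nested candidates are penalized on a common
#' scale). With `phi_reference = 1` this reduces to the Poisson AIC.
#'
#' @param fit a `qp_fit`.
#' @param phi_reference positive dispersion (default: the fit's own).
#' @return scalar QAIC (smaller is better).
#' @export
qaic <- function(fit, phi_reference = fit$dispersion) {
  if (!is.finite(phi_reference) || phi_reference <= 0) {
    stop("phi_reference must be positive")
  }
  -2 * fit$qll / phi_reference + 2 * fit$rank
}
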