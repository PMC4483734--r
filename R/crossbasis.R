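#' Default lag-space NCS spec with equally spaced knots
#'
#' Interior knots equally spaced on the lag scale between 0 and `max_lag`;
#' boundary knots at 0 and `max_lag`.
#'
#' @param max_lag maximum lag (days), >= 1.
#' @param df NCS columns in lag space (the realized lag basis adds an
#'   intercept column on top; see [lag_basis()]). `df = 0` requests an
#'   intercept-only (constant) lag structure.
#' @return a `basis_spec` of kind `ncs`, or `NULL` when `df = 0`.
#' @export
lag_knots <- function(max_lag, df = 2L) {
  df <- as.integer(df)
  if (df == 0L) return(NULL)
  if (max_lag < 1L) stop("max_lag must be >= 1 for a spline lag basis")
  kn <- if (df > 1L) seq(0, max_lag, length.out = df + 1L)[seq(2L, df)] else numeric(0)
  basis_spec("ncs", df = df, knots = kn, boundary = c(0, max_lag))
}

#' Lag-space basis matrix over lags 0..max_lag
#'
#' The lag basis always carries a leading intercept column so a constant lag
#' structure is representable; NCS columns (if any) follow.
#'
#' @param lag_spec a `basis_spec` over the lag scale, or `NULL` for
#'   intercept only.
#' @param max_lag maximum lag L (days), >= 0.
#' @return matrix with `max_lag + 1` rows (lags 0..L) and `1 + basis_df(lag_spec)`
#'   columns (1 when `lag_spec` is `NULL` or `max_lag` is 0).
#' @export
lag_basis <- function(lag_spec, max_lag) {
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("max_lag must be >= 0")
  lags <- 0:max_lag
  if (is.null(lag_spec) || max_lag == 0L) {
    C <- matrix(1, nrow = length(lags), ncol = 1L)
    colnames(C) <- "l0"
    return(C)
  }
  C <- cbind(1, eval_basis(lag_spec, lags))
  colnames(C) <- paste0("l", seq_len(ncol(C)) - 1L)
  C
}

#' Build an exposure-lag cross-basis
#'
#' Realizes the bidimensional DLNM design block: with predictor basis
#' functions `b_j` and lag basis functions `c_k` (rows of [lag_basis()]),
#' column (j, k) at time t is `sum_{l=0..L} b_j(x[t-l]) * c_k(l)`.
#' The first L rows of the source series have incomplete lag history and are
#' dropped (never padded); their exclusion is recorded in `usable_rows` so
#' the response and covariates can be subset consistently.
#'
#' @param x daily exposure series (degrees C).
#' @param pred_spec predictor-space `basis_spec`.
#' @param lag_spec lag-space `basis_spec` (or `NULL` for a constant lag
#'   structure).
#' @param max_lag maximum lag L in days (`0 <= L < length(x)`).
#' @return An object of class `crossbasis`: list with `matrix`
#'   (`(n - L) x (vx * vl)`, columns ordered with the lag index fastest),
#'   `pred_spec`, `lag_spec`, `max_lag`, `usable_rows`, `vx`, `vl`, and
#'   `col_index` mapping each column to its (j, k) pair.
#' @export
build_crossbasis <- function(x, pred_spec, lag_spec = NULL, max_lag = 13L) {
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("max_lag must be >= 0")
  n <- length(x)
  if (max_lag >= n) stop("max_lag (", max_lag, ") must be smaller than the series length (", n, ")")
  C <- lag_basis(lag_spec, max_lag)
  vl <- ncol(C)
  vx <- basis_df(pred_spec)
  usable <- seq.int(max_lag + 1L, n)
  W <- matrix(0, nrow = length(usable), ncol = vx * vl)
  jrep <- rep(seq_len(vx), each = vl)
  krep <- rep(seq_len(vl), times = vx)
  for (l in 0:max_lag) {
    Bl <- eval_basis(pred_spec, x[usable - l])
    W <- W + Bl[, jrep, drop = FALSE] *
      matrix(C[l + 1L, krep], nrow = length(usable), ncol = vx * vl, byrow = TRUE)
  }
  colnames(W) <- paste0("cb", jrep, ".", krep)
  structure(list(matrix = W, pred_spec = pred_spec, lag_spec = lag_spec,
                 max_lag = max_lag, usable_rows = usable, vx = vx, vl = vl,
                 col_index = data.frame(col = seq_len(vx * vl), j = jrep, k = krep)),
            class = "crossbasis")
}

# Contrast matrix for a set of temperatures against a reference.
# Row per temperature, column layout identical to build_crossbasis.
# cumulative: (b_j(temp) - b_j(ref)) * sum_l c_k(l)
# lag_specific: (b_j(temp) - b_j(ref)) * c_k(lag)
contrast_matrix <- function(pred_spec, lag_spec, max_lag, temps, ref,
                            mode = c("cumulative", "lag_specific"), lag = NULL) {
  mode <- match.arg(mode)
  C <- lag_basis(lag_spec, max_lag)
  vl <- ncol(C)
  vx <- basis_df(pred_spec)
  if (mode == "cumulative") {
    w <- colSums(C)
  } else {
    if (is.null(lag) || lag < 0L || lag > max_lag) {
      stop("lag_specific mode requires a lag in [0, max_lag]")
    }
    w <- C[as.integer(lag) + 1L, ]
  }
  B <- eval_basis(pred_spec, temps)
  Bref <- eval_basis(pred_spec, ref)
  D <- sweep(B, 2L, as.numeric(Bref), "-")
  M <- D[, rep(seq_len(vx), each = vl), drop = FALSE] *
    matrix(rep(w, times = vx), nrow = length(temps), ncol = vx * vl, byrow = TRUE)
  colnames(M) <- paste0("cb", rep(seq_len(vx), each = vl), ".",
                        rep(seq_len(vl), times = vx))
  M
}

#' Coefficient contrast for a temperature against a reference
#'
#' Contracting the returned vector with the fitted cross-basis coefficients
#' gives the log relative risk of `temp` versus `ref` -- cumulated over the
#' whole lag window (`mode = "cumulative"`) or at a single lag
#' (`mode = "lag_specific"`). Cumulative contrasts are exactly the sum of the
#' lag-specific ones.
#'
#' @param pred_spec,lag_spec,max_lag frozen specs defining the cross-basis.
#' @param temp temperature of interest (degrees C).
#' @param ref reference temperature (degrees C).
#' @param mode `"cumulative"` or `"lag_specific"`.
#' @param lag lag day (required for `lag_specific`).
#' @return numeric vector of length `vx * vl`.
#' @export
crossbasis_contrast <- function(pred_spec, lag_spec, max_lag, temp, ref,
                                mode = c("cumulative", "lag_specific"),
                                lag = NULL) {
  drop(contrast_matrix(pred_spec, lag_spec, max_lag, temp, ref,
                       match.arg(mode), lag))
}
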