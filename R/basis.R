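#' Declare a one-dimensional basis
#'
#' A `basis_spec` is a frozen, serializable description of a predictor- or
#' lag-space basis. Freezing the knots in the spec (rather than recomputing
#' them from whatever data the basis is evaluated on) is what makes
#' prediction-time evaluation consistent with fit-time evaluation.
#'
#' Kinds:
#' \describe{
#'   \item{`ncs`}{natural (restricted) cubic spline: cubic between knots,
#'     C2-continuous, linear beyond the boundary knots. `df` columns, with
#'     `df - 1` interior knots.}
#'   \item{`sthr`}{single high threshold ("hockey stick"): one column
#'     `max(0, x - high)`. Zero at and below the threshold.}
#'   \item{`dthr`}{double threshold: cold arm `max(0, low - x)` and heat arm
#'     `max(0, x - high)`; both zero on the closed null region
#'     `[low, high]`.}
#'   \item{`linear`}{identity, one column.}
#' }
#'
#' @param kind one of `"ncs"`, `"sthr"`, `"dthr"`, `"linear"`.
#' @param df number of basis columns (ncs only; inferred from `knots` when
#'   those are given).
#' @param knots interior knot positions (ncs only), strictly inside
#'   `boundary`.
#' @param boundary length-2 boundary knots (ncs only).
#' @param thresholds named list or vector with elements `low` and/or `high`
#'   (sthr: exactly one, `high`; dthr: both, with `low < high`).
#' @return an object of class `basis_spec`.
#' @export
basis_spec <- function(kind = c("ncs", "sthr", "dthr", "linear"),
                       df = NULL, knots = NULL, boundary = NULL,
                       thresholds = NULL) {
  kind <- match.arg(kind)
  spec <- list(kind = kind)
  if (kind == "ncs") {
    knots <- sort(as.numeric(knots))
    if (is.null(boundary) || length(boundary) != 2L || !all(is.finite(boundary)) ||
        boundary[1L] >= boundary[2L]) {
      stop("ncs basis requires finite boundary knots with boundary[1] < boundary[2]")
    }
    if (length(knots) && (min(knots) <= boundary[1L] || max(knots) >= boundary[2L])) {
      stop("interior knots must lie strictly inside the boundary knots")
    }
    if (is.null(df)) df <- length(knots) + 1L
    if (df != length(knots) + 1L) {
      stop("ncs df must equal number of interior knots + 1")
    }
    spec$df <- as.integer(df)
    spec$knots <- knots
    spec$boundary <- as.numeric(boundary)
  } else if (kind == "sthr") {
    th <- as.list(thresholds)
    if (is.null(th$high) || length(th$high) != 1L || !is.finite(th$high)) {
      stop("sthr basis requires a single finite 'high' threshold")
    }
    spec$thresholds <- list(high = as.numeric(th$high))
  } else if (kind == "dthr") {
    th <- as.list(thresholds)
    if (is.null(th$low) || is.null(th$high)) {
      stop("dthr basis requires both 'low' and 'high' thresholds")
    }
    if (!(th$low < th$high)) stop("dthr requires low < high")
    spec$thresholds <- list(low = as.numeric(th$low), high = as.numeric(th$high))
  }
  structure(spec, class = "basis_spec")
}

#' Default NCS spec with knots at equally spaced quantiles
#'
#' Places the `df - 1` interior knots at the `i/df` quantiles of `x`
#' (type-7 rule) and the boundary knots at the range of `x`.
#'
#' @param x numeric data the basis will be fitted on.
#' @param df number of basis columns, >= 1.
#' @return a frozen `basis_spec` of kind `ncs`.
#' @export
default_knots <- function(x, df) {
  if (!all(is.finite(x))) stop("x contains non-finite values")
  df <- as.integer(df)
  if (df < 1L) stop("df must be >= 1")
  nd <- length(unique(x))
  if (nd <= df) stop("df (", df, ") must be smaller than the number of distinct values (", nd, ")")
  probs <- seq_len(df - 1L) / df
  kn <- if (df > 1L) stats::quantile(x, probs, type = 7, names = FALSE) else numeric(0)
  basis_spec("ncs", df = df, knots = kn, boundary = range(x))
}

#' Natural cubic spline basis
#'
#' Restricted-cubic (truncated-power) parameterization: with full knot
#' sequence xi_1 < ... < xi_K (boundary + interior), the columns are `x` and
#' `d_k(x) - d_{K-1}(x)` for k = 1..K-2, where
#' `d_k(x) = [(x - xi_k)_+^3 - (x - xi_K)_+^3] / (xi_K - xi_k)`.
#' The cubic and quadratic terms cancel beyond the boundary knots, so every
#' column is exactly linear outside `[xi_1, xi_K]`. The intercept is not
#' included. Evaluation is a pure function of `(x, spec)`.
#'
#' @param x numeric vector (finite).
#' @param spec an ncs `basis_spec` (see [basis_spec()], [default_knots()]).
#' @return numeric matrix, `length(x)` rows by `spec$df` columns.
#' @export
ncs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"), spec$kind == "ncs")
  if (!all(is.finite(x))) stop("x contains non-finite values")
  kn <- sort(unique(c(spec$boundary[1L], spec$knots, spec$boundary[2L])))
  K <- length(kn)
  if (K == 2L) {
    out <- matrix(x, ncol = 1L)
    colnames(out) <- "b1"
    return(out)
  }
  dfun <- function(k) {
    (pmax(x - kn[k], 0)^3 - pmax(x - kn[K], 0)^3) / (kn[K] - kn[k])
  }
  dlast <- dfun(K - 1L)
  out <- cbind(x, matrix(vapply(seq_len(K - 2L), function(k) dfun(k) - dlast,
                                numeric(length(x))), nrow = length(x)))
  colnames(out) <- paste0("b", seq_len(ncol(out)))
  out
}

#' Single-high-threshold (hockey-stick) basis
#'
#' One column, `max(0, x - threshold_high)`. The threshold itself and all
#' temperatures below it contribute zero, so the fitted RR is exactly 1
#' throughout the closed null region.
#'
#' @param x numeric vector (degrees C).
#' @param threshold_high threshold (degrees C).
#' @return matrix `length(x)` x 1.
#' @export
sthr_basis <- function(x, threshold_high) {
  if (!all(is.finite(x))) stop("x contains non-finite values")
  if (!is.finite(threshold_high)) stop("threshold must be finite")
  out <- matrix(pmax(0, x - threshold_high), ncol = 1L)
  colnames(out) <- "heat"
  out
}

#' Double-threshold basis
#'
#' Cold arm `max(0, t_low - x)` and heat arm `max(0, x - t_high)`; both zero
#' on the closed null region `[t_low, t_high]`.
#'
#' @param x numeric vector (degrees C).
#' @param t_low,t_high thresholds, `t_low < t_high`.
#' @return matrix `length(x)` x 2 with columns `cold`, `heat`.
#' @export
dthr_basis <- function(x, t_low, t_high) {
  if (!all(is.finite(x))) stop("x contains non-finite values")
  if (!(is.finite(t_low) && is.finite(t_high))) stop("thresholds must be finite")
  if (!(t_low < t_high)) stop("t_low must be < t_high")
  out <- cbind(cold = pmax(0, t_low - x), heat = pmax(0, x - t_high))
  out
}

#' Evaluate any basis spec on data
#'
#' @param spec a `basis_spec`.
#' @param x numeric vector.
#' @return basis matrix with `basis_df(spec)` columns.
#' @export
eval_basis <- function(spec, x) {
  stopifnot(inherits(spec, "basis_spec"))
  switch(spec$kind,
    ncs = ncs_basis(x, spec),
    sthr = sthr_basis(x, spec$thresholds$high),
    dthr = dthr_basis(x, spec$thresholds$low, spec$thresholds$high),
    linear = {
      if (!all(is.finite(x))) stop("x contains non-finite values")
      matrix(x, ncol = 1L, dimnames = list(NULL, "b1"))
    }
  )
}

#' Number of columns a basis spec produces
#' @param spec a `basis_spec`.
#' @return integer column count.
#' @export
basis_df <- function(spec) {
  switch(spec$kind, ncs = spec$df, sthr = 1L, dthr = 2L, linear = 1L)
}
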