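# Shared fixtures: small, fast synthetic configurations.

# 2-year series with a single-high-threshold truth; omega close to the
# all-cause calibration.
small_sthr_config <- function(omega = 1.5, heat_slope = log(1.10),
                              n_years = 2) {
  synth_config(n_years = n_years,
               mortality = list(overdispersion = omega),
               surface = truth_surface("sthr", threshold_high = 30,
                                       heat_slope = heat_slope))
}

small_null_config <- function(n_years = 2) {
  synth_config(n_years = n_years, surface = truth_surface("null"))
}

# Deterministic tiny series for IO tests: 10 days, two categories.
tiny_series <- function(n = 10) {
  mortality_ts(seq(as.Date("2006-01-01"), by = "day", length.out = n),
               tmean = seq(26, 31, length.out = n),
               rh = rep(75, n),
               deaths = data.frame(all = rep(5L, n), cvd = rep(2L, n)))
}

write_tiny_csv <- function(path, n = 5) {
  df <- data.frame(date = format(seq(as.Date("2006-01-01"), by = "day",
                                     length.out = n)),
                   tmean = seq(27, 29, length.out = n),
                   rh = 70 + seq_len(n),
                   all = 50L + seq_len(n))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}

# Independent truncated-power construction of the natural cubic spline
# space: full cubic truncated-power basis, constrained to be linear beyond
# the boundary knots via an explicit null-space computation. Used as an
# oracle for the column space of ncs_basis.
natural_space_oracle <- function(x, interior, boundary) {
  kn <- sort(c(boundary, interior))
  # full truncated power cubic basis: 1, x, x^2, x^3, (x - k)^3_+
  Tp <- cbind(1, x, x^2, x^3,
              sapply(kn, function(k) pmax(x - k, 0)^3))
  # natural constraints: second and third derivative vanish beyond both
  # boundaries. Below the lower boundary all (x-k)^3_+ vanish, so the
  # global quadratic and cubic coefficients must be zero; above the upper
  # boundary the quadratic and cubic parts of the expanded polynomial must
  # cancel: sum of cubic coefs = 0 and sum of k * cubic coefs = 0.
  m <- length(kn)
  Amat <- rbind(
    c(0, 0, 1, 0, rep(0, m)),        # global x^2 coef
    c(0, 0, 0, 1, rep(0, m)),        # global x^3 coef
    c(0, 0, 0, 1, rep(1, m)),        # total cubic coef above upper boundary
    c(0, 0, 1, 0, -3 * kn)           # total quadratic coef above upper boundary
  )
  ns_dir <- svd(Amat, nv = ncol(Amat))$v[, (qr(Amat)$rank + 1):ncol(Amat)]
  Tp %*% ns_dir
}

# Max abs residual of projecting each column of A onto the column space of B.
projection_residual <- function(A, B) {
  fit <- lm.fit(B, A)
  max(abs(as.matrix(fit$residuals)))
}
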