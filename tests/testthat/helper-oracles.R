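# Independent oracles, deliberately coded without lm(), uniroot() or any
# package internals, so they can cross-check the implementation.

# closed-form simple linear regression via explicit sums
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y); syy <- sum(y * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  ss_res <- sum((y - intercept - slope * x)^2)
  slope_se <- sqrt(ss_res / (n - 2) / (sxx - sx^2 / n))
  list(slope = slope, intercept = intercept, r = r, slope_se = slope_se)
}

# hand-rolled bisection for D solving fa/fu = (D/Dm)^m at a given fa
bisect_dose <- function(dm, m, fa, lo = 1e-12, hi = 1e6, iter = 200) {
  target <- fa / (1 - fa)
  f <- function(d) (d / dm)^m - target
  for (i in seq_len(iter)) {
    mid <- sqrt(lo * hi) # geometric bisection: dose spans many decades
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

# hand-rolled bisection for the fa at which a fixed-ratio mixture dose D
# attains combination index `ci` against two single-agent curves
bisect_loewe_fa <- function(d1, d2, dm1, m1, dm2, m2, ci, iter = 200) {
  dx <- function(dm, m, fa) dm * (fa / (1 - fa))^(1 / m)
  g <- function(fa) d1 / dx(dm1, m1, fa) + d2 / dx(dm2, m2, fa) - ci
  lo <- 1e-12; hi <- 1 - 1e-12
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
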