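# Independent brute-force oracle for the one-sided Bayes factor: dense
# trapezoid integration of the noncentral-t density against the truncated,
# doubled Cauchy prior on the effect-size scale.  Deliberately naive — no
# change of variable, no log-space tricks — so it shares nothing with the
# production quadrature beyond the integrand definition.
bf10_trapezoid <- function(t, n, r, n_grid = 150000L) {
  df <- n - 1
  # the noncentral-t density in delta is negligible beyond the likelihood
  # core; at small df the density decays slowly in the noncentrality
  # (like exp(-mu^2 df / (2 (df + t^2)))), so the core widens accordingly
  lo <- -((abs(t) + 14) * sqrt((df + t^2) / df) / sqrt(n) + 12 * r)
  d <- seq(lo, 0, length.out = n_grid)
  f <- suppressWarnings(dt(t, df, ncp = d * sqrt(n))) * 2 * dcauchy(d, 0, r)
  h <- d[2L] - d[1L]
  m1 <- h * (sum(f) - (f[1L] + f[n_grid]) / 2)
  m1 / dt(t, df)
}

# Closed-form inverse-variance pooling for a handful of studies, used as the
# oracle for the meta-analysis module.
pool_fixed <- function(d, v) {
  w <- 1 / v
  es <- sum(w * d) / sum(w)
  list(es = es, se = sqrt(1 / sum(w)),
       Q = sum(w * (d - es)^2))
}
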