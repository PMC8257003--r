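# Independent oracles used across the suite.

# Brute-force Bayes on a grid: binomial likelihood times prior density,
# normalized by trapezoidal integration. The conjugate update must agree
# pointwise with this.
grid_posterior <- function(alpha0, beta0, k, n, npts = 1001) {
  x <- seq(0, 1, length.out = npts)
  unnorm <- stats::dbinom(k, n, x) * stats::dbeta(x, alpha0, beta0)
  list(x = x, density = unnorm / trapz_norm(unnorm, x))
}

trapz_norm <- function(y, x) {
  sum((y[-1] + y[-length(y)]) / 2) * (x[2] - x[1])
}

# Literal sliding-window stabilization detector: enumerate every window,
# scale the slope by 10,000, round half away from zero, and scan for the
# first start followed by 50 consecutive zero windows.
brute_stabilization <- function(series, n_iter) {
  omega <- n_iter / 10
  rnd <- function(x) sign(x) * floor(abs(x) + 0.5)
  g_max <- n_iter - omega
  t_g <- sapply(0:g_max, function(g)
    rnd((series[g + omega + 1] - series[g + 1]) / omega * 10000))
  for (g in 0:(g_max - 50)) {
    if (all(t_g[(g + 1):(g + 51)] == 0))
      return(list(stab_tick = g, stabilized = TRUE))
  }
  list(stab_tick = n_iter, stabilized = FALSE)
}

# Membership agreement with a planted partition (adjusted Rand).
rand_agreement <- function(a, b) {
  igraph::compare(a, b, method = "adjusted.rand")
}

# Number of adjacent-pair monotonicity violations in a vector.
n_inversions <- function(v, increasing = TRUE) {
  d <- diff(v)
  if (increasing) sum(d < 0) else sum(d > 0)
}
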