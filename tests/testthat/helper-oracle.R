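# Independent brute-force oracle for the exponential decay fit: exhaustive
# grid search over (a, k) minimizing the same sum of squared errors. For
# each k the SSE is quadratic in a, so the k-slice is evaluated on the a
# grid in one vectorized sweep. Deliberately shares no code with
# fit_decay().
grid_search_decay <- function(ep, a_grid = seq(1, 60, by = 0.01),
                              k_grid = seq(0.5, 1.1, by = 0.001)) {
  n <- seq_along(ep) - 1
  best <- list(sse = Inf, a = NA_real_, k = NA_real_)
  c0 <- sum(ep^2)
  for (k in k_grid) {
    kn <- k^n
    c1 <- sum(ep * kn)
    c2 <- sum(kn * kn)
    sse <- c0 - 2 * a_grid * c1 + a_grid^2 * c2
    i <- which.min(sse)
    if (sse[i] < best$sse) {
      best <- list(sse = sse[i], a = a_grid[i], k = k)
    }
  }
  best
}

# SSE of the package model at given parameters, for oracle comparisons.
decay_sse <- function(ep, a, k) {
  n <- seq_along(ep) - 1
  sum((ep - a * k^n)^2)
}

# Geometric epCO2 series with multiplicative Gaussian noise, the cohort
# simulation ingredient used across decay and cohort tests.
sim_ep_series <- function(ep0, k, N, noise_frac = 0.03) {
  n <- seq_len(N) - 1
  ep0 * k^n * (1 + rnorm(N, 0, noise_frac))
}
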