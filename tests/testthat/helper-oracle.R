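# Independent brute-force implementation of the direct multifractal
# estimator, written as literally as possible: explicit loops, direct
# powers (no log-domain tricks), slopes from lm(). Only valid for strictly
# positive series and moderate |q|; it exists to cross-check the package's
# optimised path, never to share code with it.

naive_bin_proportions <- function(u, L) {
  n_bins <- floor(length(u) / L)
  P <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    P[i] <- sum(u[((i - 1) * L + 1):(i * L)])
  }
  P / sum(P)
}

naive_spectrum <- function(u, scales, q_values) {
  alpha <- numeric(length(q_values))
  f <- numeric(length(q_values))
  for (j in seq_along(q_values)) {
    q <- q_values[j]
    f_num <- numeric(length(scales))
    a_num <- numeric(length(scales))
    for (s in seq_along(scales)) {
      P <- naive_bin_proportions(u, scales[s])
      mu <- P^q / sum(P^q)
      f_num[s] <- sum(mu * log(mu))
      a_num[s] <- sum(mu * log(P))
    }
    lnL <- log(scales)
    f[j] <- unname(coef(lm(f_num ~ lnL))[2])
    alpha[j] <- unname(coef(lm(a_num ~ lnL))[2])
  }
  list(q = q_values, alpha = alpha, f = f)
}

# one-sided periodogram (positive frequencies, no DC)
periodogram <- function(x) {
  n <- length(x)
  Mod(stats::fft(x))[2:(n %/% 2)]^2
}

# small, fast scaling configuration for structural tests where the exact
# q sweep is not the thing under test
fast_cfg <- function(l_max = NULL) {
  scaling_config(q_values = seq(-20, 20, by = 2), l_max = l_max)
}
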