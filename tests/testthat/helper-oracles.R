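# Independent oracles used across the test files.

# e-value by direct Monte Carlo, independent of the package's code paths
mc_evalue_oracle <- function(A1, A2, gamma0, M = 2e5) {
  kappa <- rbeta(M, A1, A2)
  mean(dbeta(kappa, A1, A2) <= dbeta(gamma0, A1, A2))
}

# naive leave-one-out for the exponential-gamma model: full refit per row
naive_exp_loo <- function(x, a, b, gamma) {
  t(vapply(seq_along(x), function(i) {
    m <- exp_gamma_model(x = x[-i], a = a, b = b)
    ci <- exp_equal_tailed_ci(m, gamma)
    c(lower = ci$lower, upper = ci$upper,
      covered = coverage_indicator(x[i], ci))
  }, numeric(3)))
}

# brute-force HPD: examine every window of ceiling(gamma*J) consecutive
# order statistics
brute_hpd <- function(draws, gamma) {
  s <- sort(draws)
  J <- length(s)
  m <- ceiling(gamma * J)
  best <- c(Inf, NA, NA)
  for (i in 1:(J - m + 1)) {
    w <- s[i + m - 1] - s[i]
    if (w < best[1]) best <- c(w, s[i], s[i + m - 1])
  }
  best[2:3]
}
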