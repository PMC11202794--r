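test_that("posterior update follows the Beta-Bernoulli rule", {
  cases <- list(
    list(a1 = 1, a2 = 1, u = rep(c(1, 0), c(47, 53)), A1 = 48, A2 = 54),
    list(a1 = 1, a2 = 1, u = rep(c(1, 0), c(11, 22)), A1 = 12, A2 = 23),
    list(a1 = 0.5, a2 = 0.5, u = 1, A1 = 1.5, A2 = 0.5)
  )
  for (cs in cases) {
    post <- beta_posterior(u = cs$u, a1 = cs$a1, a2 = cs$a2)
    expect_identical(post$A1, cs$A1)
    expect_identical(post$A2, cs$A2)
    expect_identical(post$u_sum, as.integer(sum(cs$u)))
    expect_identical(post$A1, cs$a1 + post$u_sum)
    expect_identical(post$A2, cs$a2 + post$n - post$u_sum)
  }
  # count-based input agrees with vector input
  expect_equal(beta_posterior(n = 100, u_sum = 47),
               beta_posterior(u = rep(c(1, 0), c(47, 53))))
  expect_error(beta_posterior(u = c(1, 2)), "0/1")
  expect_error(beta_posterior(u = c(1, 0), a1 = 0), "positive")
  expect_error(beta_posterior(u = numeric(0)), "non-empty")
})

test_that("analytic e-values reproduce the worked coverage cases", {
  # frozen from the exact tail-mass computation, cross-checked by MC below
  expect_equal(e_value(beta_posterior(n = 100, u_sum = 47))$e_value,
               0.545404, tolerance = 1e-5)
  expect_equal(e_value(beta_posterior(n = 30, u_sum = 9))$e_value,
               0.023086, tolerance = 1e-5)
  expect_equal(e_value(beta_posterior(n = 33, u_sum = 11))$e_value,
               0.048337, tolerance = 1e-5)
})

test_that("e-value is 1 exactly when gamma0 sits at the posterior mode", {
  post <- beta_posterior(n = 10, u_sum = 5)  # Beta(6, 6), mode 0.5
  expect_identical(e_value(post, 0.5)$e_value, 1)
  set.seed(4)
  expect_identical(e_value(post, 0.5, method = "mc", M = 1e4)$e_value, 1)
})

test_that("Monte Carlo and analytic e-values agree within MC error", {
  set.seed(42)
  grid <- expand.grid(n = c(10, 33, 100), frac = c(0.2, 0.35, 0.5, 0.7))
  M <- 2e5
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]
    post <- beta_posterior(n = n, u_sum = round(grid$frac[i] * n))
    ea <- e_value(post, 0.5)$e_value
    em <- e_value(post, 0.5, method = "mc", M = M)$e_value
    tol <- 4 * sqrt(max(ea * (1 - ea), 1e-6) / M)
    expect_lt(abs(ea - em), tol + 1e-12)
  }
})

test_that("e-values are symmetric and monotone on the achievable grid", {
  for (n in c(10, 23, 40)) {
    ev <- vapply(0:n, function(u) {
      e_value(beta_posterior(n = n, u_sum = u), 0.5)$e_value
    }, numeric(1))
    # symmetry under u <-> n - u at gamma0 = 0.5 with the uniform prior
    expect_equal(ev, rev(ev), tolerance = 1e-9)
    # non-increasing as |u/n - 0.5| grows
    lower_half <- ev[1:(floor(n / 2) + 1)]
    expect_true(all(diff(lower_half) >= -1e-9))
    expect_true(all(ev >= 0 & ev <= 1))
  }
})

test_that("monotone and U-shaped posterior densities are handled exactly", {
  # decreasing density (A1 <= 1 < A2): level set is the upper tail
  expect_equal(predacc:::evalue_analytic(1, 5, 0.3),
               pbeta(0.3, 1, 5, lower.tail = FALSE))
  # increasing density (A2 <= 1 < A1): level set is the lower tail
  post <- beta_posterior(u = 1, a1 = 0.5, a2 = 0.5)  # Beta(1.5, 0.5)
  expect_equal(e_value(post, 0.4)$e_value, pbeta(0.4, 1.5, 0.5))
  # flat Beta(1, 1): every point has the maximal density
  expect_identical(predacc:::evalue_analytic(1, 1, 0.37), 1)
  # U-shaped: cross-check against direct Monte Carlo
  set.seed(9)
  ea <- predacc:::evalue_analytic(0.4, 0.7, 0.3)
  em <- mc_evalue_oracle(0.4, 0.7, 0.3, M = 2e5)
  expect_lt(abs(ea - em), 4 * sqrt(ea * (1 - ea) / 2e5))
})

test_that("the FBST decision uses a strict inequality", {
  expect_identical(fbst_decision(0.545, alpha = 0.05), "not_reject")
  expect_identical(fbst_decision(0.023, alpha = 0.05), "reject")
  expect_identical(fbst_decision(0.05, alpha = 0.05), "not_reject")
  res <- e_value(beta_posterior(n = 30, u_sum = 9))
  expect_identical(fbst_decision(res, 0.05), "reject")
  expect_error(fbst_decision(0.5, alpha = 0), "alpha")
  expect_error(e_value(beta_posterior(n = 10, u_sum = 5), gamma0 = 1),
               "gamma0")
})
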