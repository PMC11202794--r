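test_that("log posterior matches the exponential likelihood", {
  y <- 1
  X <- matrix(1, 1, 1)
  # intercept-only, beta = 0: loglik = -eta - y exp(-eta) = -1
  expect_equal(log_posterior_expreg(0, y, X, include_prior = FALSE), -1)
  # prior adds the normal log density
  expect_equal(log_posterior_expreg(0, y, X, prior_mean = 0, prior_sd = 100),
               -1 + dnorm(0, 0, 100, log = TRUE))
  # non-finite linear predictor is an impossible move, not an error
  expect_identical(log_posterior_expreg(-1000, y, X), -Inf)
  # log-posterior differences are the Metropolis log-ratio
  set.seed(6)
  y2 <- rexp(10, 0.5)
  X2 <- cbind(1, rnorm(10))
  b1 <- c(0.5, 0.1); b2 <- c(0.7, -0.2)
  expect_equal(
    log_posterior_expreg(b2, y2, X2) - log_posterior_expreg(b1, y2, X2),
    (log_posterior_expreg(b2, y2, X2, include_prior = FALSE) +
       sum(dnorm(b2, 0, 100, log = TRUE))) -
      (log_posterior_expreg(b1, y2, X2, include_prior = FALSE) +
         sum(dnorm(b1, 0, 100, log = TRUE)))
  )
})

test_that("analytic gradient matches finite differences", {
  set.seed(21)
  y <- rexp(30, 0.4)
  X <- cbind(1, runif(30, 0, 3), rbinom(30, 1, 0.5))
  beta <- c(0.8, -0.2, 0.4)
  g <- predacc:::grad_log_posterior_expreg(beta, y, X, rep(0, 3), rep(100, 3))
  eps <- 1e-6
  g_num <- vapply(1:3, function(j) {
    e <- rep(0, 3); e[j] <- eps
    (log_posterior_expreg(beta + e, y, X) -
       log_posterior_expreg(beta - e, y, X)) / (2 * eps)
  }, numeric(1))
  expect_equal(g, g_num, tolerance = 1e-5)
})

test_that("chains are bit-reproducible and correctly sized", {
  d <- leukemia_data()
  f1 <- fit_exp_reg(time ~ wbc + ag, d, n_iter = 6000, burn_in = 1000,
                    thin = 5, seed = 99)
  f2 <- fit_exp_reg(time ~ wbc + ag, d, n_iter = 6000, burn_in = 1000,
                    thin = 5, seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_identical(nrow(f1$draws), as.integer((6000 - 1000) / 5))
  expect_gt(f1$acceptance_rate, 0.02)
  expect_lt(f1$acceptance_rate, 1)
  expect_error(fit_exp_reg(time ~ wbc, transform(d, time = time - 10)),
               "positive")
  expect_error(fit_exp_reg(time ~ wbc, d, n_iter = 100, burn_in = 200),
               "burn_in")
})

test_that("a near-degenerate prior pins the coefficients", {
  d <- leukemia_data()
  f <- fit_exp_reg(time ~ wbc + ag, d, prior_mean = c(2, 0.5, -1),
                   prior_sd = 1e-6, n_iter = 4000, burn_in = 1000,
                   thin = 1, seed = 3)
  expect_equal(unname(colMeans(f$draws)), c(2, 0.5, -1), tolerance = 1e-3)
})

test_that("the sampler recovers known coefficients", {
  set.seed(55)
  n <- 400
  x1 <- runif(n, 0, 3)
  eta <- 1 + 0.5 * x1
  d <- data.frame(y = rexp(n, rate = exp(-eta)), x1 = x1)
  f <- fit_exp_reg(y ~ x1, d, n_iter = 30000, burn_in = 3000, thin = 5,
                   seed = 56)
  pm <- colMeans(f$draws)
  psd <- apply(f$draws, 2, sd)
  expect_lt(abs(pm[1] - 1), 3 * psd[1])
  expect_lt(abs(pm[2] - 0.5), 3 * psd[2])
})

test_that("intercept-only predictive matches the conjugate closed form", {
  set.seed(23)
  x <- rexp(50, rate = 0.25)
  d <- data.frame(y = x)
  f <- fit_exp_reg(y ~ 1, d, prior_sd = 100, n_iter = 60000, burn_in = 5000,
                   thin = 5, seed = 24)
  ci_mcmc <- predict_interval(f, d[1, , drop = FALSE], gamma = 0.5)
  # vague Gamma prior: the conjugate posterior reduces to the likelihood
  m <- exp_gamma_model(x = x, a = 1e-4, b = 1e-4)
  ci_conj <- exp_equal_tailed_ci(m, 0.5)
  expect_equal(ci_mcmc$lower, ci_conj$lower, tolerance = 0.05)
  expect_equal(ci_mcmc$upper, ci_conj$upper, tolerance = 0.05)
})

test_that("predictive draws from a concentrated posterior are exponential", {
  d <- data.frame(y = rexp(20, 1))
  b0 <- log(10)  # mean response 10
  f <- fit_exp_reg(y ~ 1, d, prior_mean = b0, prior_sd = 1e-8,
                   n_iter = 42000, burn_in = 2000, thin = 1, seed = 12)
  set.seed(13)
  draws <- predictive_draws(f, d[1, , drop = FALSE])
  expect_length(draws, nrow(f$draws))
  expect_equal(mean(draws), 10, tolerance = 0.04)
  expect_equal(median(draws), 10 * log(2), tolerance = 0.04)
})
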