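test_that("exponential-gamma predictive density is a proper density", {
  m <- exp_gamma_model(a = 1, b = 1, n = 10, sum_x = 20)
  expect_equal(
    stats::integrate(exp_predictive_density, 0, Inf, model = m)$value,
    1, tolerance = 1e-8
  )
  # Lomax(1, 1) at the support edge
  m0 <- exp_gamma_model(a = 1, b = 1, n = 0, sum_x = 0)
  expect_equal(exp_predictive_density(0, m0), 1)
  expect_identical(exp_predictive_density(-1, m0), 0)
  expect_error(exp_gamma_model(a = -1, b = 1, n = 0, sum_x = 0), "positive")
})

test_that("predictive density matches the two-stage sampling scheme", {
  set.seed(5)
  m <- exp_gamma_model(a = 0.01, b = 0.01, n = 25, sum_x = 60)
  draws <- exp_predictive_sample(1e5, m)
  ks <- suppressWarnings(
    stats::ks.test(draws, function(y) exp_predictive_cdf(y, m))
  )
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("quantile and cdf are mutual inverses to 1e-10", {
  qs <- c(0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99)
  for (m in list(exp_gamma_model(a = 1, b = 1, n = 0, sum_x = 0),
                 exp_gamma_model(a = 0.01, b = 0.01, n = 30, sum_x = 45),
                 exp_gamma_model(a = 3, b = 0.5, n = 100, sum_x = 210))) {
    yq <- exp_predictive_quantile(qs, m)
    expect_equal(exp_predictive_cdf(yq, m), qs, tolerance = 1e-10)
  }
  m0 <- exp_gamma_model(a = 1, b = 1, n = 0, sum_x = 0)
  expect_equal(exp_predictive_quantile(0.25, m0), 1 / 3)
  expect_equal(exp_predictive_quantile(0.75, m0), 3)
  expect_equal(exp_predictive_quantile(0.5, m0), 1)  # median of Lomax(1,1)
  expect_error(exp_predictive_quantile(1.2, m0), "q must")
})

test_that("equal-tailed interval has nominal coverage", {
  m0 <- exp_gamma_model(a = 1, b = 1, n = 0, sum_x = 0)
  ci <- exp_equal_tailed_ci(m0, 0.5)
  expect_equal(ci$lower, 1 / 3)
  expect_equal(ci$upper, 3)
  expect_identical(ci$realized_credibility, 0.5)
  set.seed(8)
  m <- exp_gamma_model(a = 0.01, b = 0.01, n = 40, sum_x = 90)
  ci <- exp_equal_tailed_ci(m, 0.5)
  fresh <- exp_predictive_sample(1e5, m)
  inside <- mean(fresh >= ci$lower & fresh <= ci$upper)
  expect_lt(abs(inside - 0.5), 0.01)
})

test_that("posterior updates are exchangeable and sequential", {
  set.seed(2)
  x <- rexp(20, 0.3)
  m1 <- exp_gamma_model(x = x, a = 2, b = 3)
  m2 <- exp_gamma_model(x = sample(x), a = 2, b = 3)
  expect_equal(m1$sum_x, m2$sum_x)
  # one-at-a-time updating equals the batch update
  inc <- exp_gamma_model(x = x[1], a = 2, b = 3)
  for (i in 2:20) {
    inc <- exp_gamma_model(n = inc$n + 1, sum_x = inc$sum_x + x[i],
                           a = 2, b = 3)
  }
  expect_equal(inc$n, m1$n)
  expect_equal(inc$sum_x, m1$sum_x)
})

test_that("gamma-poisson pmf matches its closed forms and dnbinom", {
  # A = B = 1 reduces to geometric(1/2)
  m <- pois_gamma_model(a = 1, b = 1, n = 0, sum_x = 0)
  expect_equal(pois_predictive_pmf(0:10, m), 0.5^(1:11))
  # general case against the negative-binomial parameterisation
  m2 <- pois_gamma_model(a = 0.01, b = 0.01, n = 30, sum_x = 501.99)
  y <- 0:80
  expect_equal(pois_predictive_pmf(y, m2),
               stats::dnbinom(y, size = m2$A, prob = m2$B / (m2$B + 1)),
               tolerance = 1e-12)
  expect_equal(pois_predictive_cdf(y, m2),
               stats::pnbinom(y, size = m2$A, prob = m2$B / (m2$B + 1)),
               tolerance = 1e-10)
  expect_error(pois_predictive_pmf(1.5, m2), "integer")
})

test_that("gamma-poisson tail truncation and moments are controlled", {
  m <- pois_gamma_model(a = 0.01, b = 0.01, n = 30, sum_x = 501.99)
  y_star <- 200
  pmf <- pois_predictive_pmf(0:y_star, m)
  expect_gte(sum(pmf), 1 - 1e-10)
  expect_equal(sum((0:y_star) * pmf), m$A / m$B, tolerance = 1e-8)
})

test_that("discrete interval limits follow the sup/inf definitions", {
  m <- pois_gamma_model(a = 502, b = 30, n = 0, sum_x = 0)
  ci <- pois_equal_tailed_limits(m, 0.5)
  expect_identical(ci$lower, 13L)
  expect_identical(ci$upper, 19L)
  expect_lt(abs(ci$realized_credibility - 0.602), 5e-4)
  expect_gte(ci$realized_credibility, 0.5)
  # realized credibility >= gamma across models and levels
  set.seed(3)
  for (rep in 1:15) {
    mm <- pois_gamma_model(a = runif(1, 0.01, 5), b = runif(1, 0.01, 5),
                           n = sample(1:50, 1), sum_x = sample(0:200, 1))
    g <- runif(1, 0.2, 0.9)
    cc <- pois_equal_tailed_limits(mm, g)
    expect_gte(cc$realized_credibility, g)
    expect_lte(cc$lower, cc$upper)
  }
  # mass concentrated at zero: the sup runs over an empty set, L1 = 0
  m0 <- pois_gamma_model(a = 1, b = 5000, n = 0, sum_x = 0)
  ci0 <- pois_equal_tailed_limits(m0, 0.5)
  expect_identical(ci0$lower, 0L)
  expect_identical(ci0$upper, 0L)
})

test_that("empirical HPD is the shortest window of order statistics", {
  set.seed(14)
  draws <- rexp(2000, 0.1)^1.3  # right-skewed
  hpd <- hpd_from_samples(draws, 0.5)
  expect_equal(c(hpd$lower, hpd$upper), brute_hpd(draws, 0.5))
  et <- quantile(draws, c(0.25, 0.75))
  expect_lt(hpd$lower, et[[1]])  # skew pulls the HPD toward the bulk
  expect_lte(hpd$upper - hpd$lower, et[[2]] - et[[1]])
  # near-symmetric sample: HPD approximately equal-tailed
  z <- rnorm(5000)
  hz <- hpd_from_samples(z, 0.5)
  qz <- quantile(z, c(0.25, 0.75))
  expect_lt(abs(hz$lower - qz[[1]]), 0.1)
  expect_lt(abs(hz$upper - qz[[2]]), 0.1)
  expect_error(hpd_from_samples(rnorm(50), 0.5), "100")
})
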