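#' Simulation scenarios for the exponential regression
#'
#' Four fixed coefficient scenarios, each with an intercept and five
#' slopes, combined with covariate laws X1 ~ Uniform(0, 5),
#' X2 ~ Bernoulli(0.2), X3 ~ Normal(0, 1), X4 ~ Bernoulli(0.7),
#' X5 ~ Uniform(0, 5). Models with k < 5 covariates use the first k
#' terms of the linear predictor.
#'
#' @return Named list of coefficient vectors (intercept first).
#' @export
sim_scenarios <- function() {
  list(
    S1 = c(-0.7, 1.1, -0.6, 0.2, 1, -1.5),
    S2 = c(1, -1.3, 0.4, -0.2, 0.9, -0.3),
    S3 = c(-0.3, 0.7, -1.2, 1.1, -0.7, 1),
    S4 = c(1.7, -0.8, 0.1, 0.6, -0.8, -1.1)
  )
}

#' Simulate one exponential-regression dataset
#'
#' Draws n covariate rows from the scenario's covariate laws, forms the
#' linear predictor from the intercept and the first `n_covariates`
#' slope terms, and draws y_i ~ Exponential(rate = exp(-x_i' beta)), so
#' that E[y_i] = exp(x_i' beta).
#'
#' @param scenario one of `"S1"`..`"S4"`, or a numeric coefficient
#'   vector (intercept first).
#' @param n_covariates number of covariates, 1..5.
#' @param n sample size (>= 2).
#' @param seed optional integer seed.
#' @return Data frame with columns `y`, `x1`, ..., `xk`.
#' @examples
#' d <- simulate_dataset("S1", n_covariates = 2, n = 50, seed = 1)
#' @export
simulate_dataset <- function(scenario = "S1", n_covariates = 5, n,
                             seed = NULL) {
  if (is.character(scenario)) {
    sc <- sim_scenarios()[[scenario]]
    if (is.null(sc)) stop_input("unknown scenario: ", scenario)
  } else {
    sc <- as.numeric(scenario)
    if (length(sc) < n_covariates + 1) {
      stop_input("coefficient vector too short for n_covariates")
    }
  }
  if (n_covariates < 1 || n_covariates > 5) {
    stop_input("n_covariates must lie in 1..5")
  }
  if (n < 2) stop_input("n must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  laws <- list(
    function(n) runif(n, 0, 5),
    function(n) rbinom(n, 1, 0.2),
    function(n) rnorm(n, 0, 1),
    function(n) rbinom(n, 1, 0.7),
    function(n) runif(n, 0, 5)
  )
  X <- sapply(laws[seq_len(n_covariates)], function(f) f(n))
  X <- matrix(X, nrow = n)
  eta <- sc[1] + drop(X %*% sc[2:(n_covariates + 1)])
  y <- rexp(n, rate = exp(-eta))
  out <- data.frame(y = y, X)
  names(out) <- c("y", paste0("x", seq_len(n_covariates)))
  out
}

#' Skewness coefficient
#'
#' Standardised third central moment m3 / m2^(3/2). Samples with zero
#' variance have undefined skewness and return `NA`.
#'
#' @param values numeric sample of at least 3 values.
#' @return The skewness coefficient, or `NA`.
#' @export
skewness <- function(values) {
  if (length(values) < 3L) stop_input("at least 3 values are required")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((values - m)^3) / m2^1.5
}

#' Simulation study of the coverage proportion
#'
#' For each cell (scenario x number of covariates x sample size),
#' simulates `reps` datasets from the exponential regression, runs the
#' full leave-one-out pipeline with equal-tailed intervals, and
#' summarises the distribution of kappa by its mean, standard deviation
#' and skewness. Diffuse N(0, 100^2) priors are used for the fits. Cells
#' default to a reduced scale suitable for exploratory runs; increase
#' `reps` and the chain settings for a full-scale study.
#'
#' @param scenarios scenario names.
#' @param n_covariates numbers of covariates, each in 1..5.
#' @param n_grid sample sizes.
#' @param reps replicates per cell.
#' @param gamma credible level of the predictive intervals.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param n_iter,burn_in,thin Metropolis settings per leave-one-out fit.
#' @return A data frame of class `sim_summary` keyed by (scenario, k, n)
#'   with columns `mean_kappa`, `sd_kappa`, `skewness_kappa`, `n_reps`,
#'   `n_failed`.
#' @export
run_study <- function(scenarios = c("S1", "S2", "S3", "S4"),
                      n_covariates = 1:5,
                      n_grid = c(10, 30, 50, 100, 150),
                      reps = 100, gamma = 0.5, seed = NULL,
                      n_iter = 20000, burn_in = 2000, thin = 5) {
  if (reps < 1) stop_input("reps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(scenario = scenarios, k = n_covariates, n = n_grid,
                       stringsAsFactors = FALSE)
  cell_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, nrow(cells) * reps),
    nrow = nrow(cells)
  )
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sc <- cells$scenario[ci]
    k <- cells$k[ci]
    n <- cells$n[ci]
    form <- stats::as.formula(
      paste("y ~", paste(paste0("x", seq_len(k)), collapse = " + "))
    )
    model <- exp_reg_model(form, n_iter = n_iter, burn_in = burn_in,
                           thin = thin)
    kappas <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      d <- simulate_dataset(sc, k, n, seed = cell_seeds[ci, r])
      kappas[r] <- tryCatch(
        run_loo(model, d, gamma = gamma, seed = cell_seeds[ci, r] %% 1e6 +
                  1L)$record$kappa,
        error = function(e) NA_real_
      )
    }
    ok <- kappas[!is.na(kappas)]
    out[[ci]] <- data.frame(
      scenario = sc, k = k, n = n,
      mean_kappa = mean(ok),
      sd_kappa = if (length(ok) > 1) sd(ok) else NA_real_,
      skewness_kappa = if (length(ok) >= 3) skewness(ok) else NA_real_,
      n_reps = length(ok),
      n_failed = sum(is.na(kappas))
    )
  }
  out <- do.call(rbind, out)
  class(out) <- c("sim_summary", class(out))
  out
}
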