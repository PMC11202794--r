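#' Log posterior of the exponential regression
#'
#' Exponential regression with rate theta_i = exp(-x_i' beta), so that
#' the mean response is exp(x_i' beta), and independent normal priors on
#' the coefficients. The log posterior (up to an additive constant) is
#' sum_i [ -x_i' beta - y_i exp(-x_i' beta) ] plus the normal prior log
#' densities. A non-finite linear predictor yields -Inf (a rejected
#' Metropolis move), not an error.
#'
#' @param beta coefficient vector.
#' @param y positive response vector.
#' @param X design matrix (including the intercept column).
#' @param prior_mean,prior_sd normal prior means and standard deviations,
#'   recycled across coefficients. Defaults are the diffuse N(0, 100^2).
#' @param include_prior `FALSE` returns the log likelihood alone.
#' @return Scalar log density.
#' @export
log_posterior_expreg <- function(beta, y, X, prior_mean = 0, prior_sd = 100,
                                 include_prior = TRUE) {
  eta <- drop(X %*% beta)
  if (any(!is.finite(eta)) || any(-eta > 700)) return(-Inf)
  ll <- sum(-eta - y * exp(-eta))
  if (!include_prior) return(ll)
  pm <- rep_len(prior_mean, length(beta))
  ps <- rep_len(prior_sd, length(beta))
  ll + sum(dnorm(beta, pm, ps, log = TRUE))
}

# gradient of the log posterior; used for the MAP initialisation
grad_log_posterior_expreg <- function(beta, y, X, prior_mean, prior_sd) {
  eta <- drop(X %*% beta)
  drop(crossprod(X, -1 + y * exp(-eta))) - (beta - prior_mean) / prior_sd^2
}

#' Fit the exponential regression by adaptive random-walk Metropolis
#'
#' Bayesian exponential regression (rate exp(-x' beta), mean exp(x' beta))
#' with independent normal priors, sampled by random-walk Metropolis on
#' the full coefficient vector. The chain is initialised at the
#' maximum-a-posteriori point (found by a short BFGS optimisation), the
#' proposal covariance is the inverse curvature at the MAP scaled by
#' 2.38^2/p, and a global scale factor is adapted in batches during
#' burn-in towards the target acceptance rate, then frozen. Chains are
#' bit-reproducible for a fixed seed.
#'
#' @param formula model formula, e.g. `time ~ wbc + ag`.
#' @param data data frame with the response and covariates; the response
#'   must be strictly positive.
#' @param prior_mean,prior_sd normal prior means and standard deviations,
#'   recycled across coefficients (default diffuse N(0, 100^2)).
#' @param n_iter total Metropolis iterations, including burn-in.
#' @param burn_in iterations discarded (and used for adaptation).
#' @param thin keep every `thin`-th post-burn-in draw; the retained chain
#'   has (n_iter - burn_in)/thin rows.
#' @param seed optional integer seed.
#' @param target_acc target acceptance rate for the adaptation.
#' @return An object of class `exp_reg_fit` with the coefficient draws
#'   (`draws`), `acceptance_rate`, `map` estimate, the chain settings and
#'   the model frame ingredients needed for prediction.
#' @examples
#' d <- leukemia_data()
#' fit <- fit_exp_reg(time ~ wbc + ag, d, n_iter = 20000, burn_in = 2000,
#'                    seed = 1)
#' colMeans(fit$draws)
#' @export
fit_exp_reg <- function(formula, data, prior_mean = 0, prior_sd = 100,
                        n_iter = 1e6, burn_in = 1e4, thin = 5, seed = NULL,
                        target_acc = 0.3) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (!is.numeric(y) || any(y <= 0)) {
    stop_input("the response must be strictly positive")
  }
  if (any(prior_sd <= 0)) stop_input("prior_sd must be positive")
  if (n_iter <= burn_in) stop_input("n_iter must exceed burn_in")
  if (thin < 1) stop_input("thin must be >= 1")
  p <- ncol(X)
  pm <- rep_len(prior_mean, p)
  ps <- rep_len(prior_sd, p)

  if (!is.null(seed)) set.seed(seed)

  # MAP initialisation and curvature-based proposal covariance
  opt <- optim(rep(0, p),
               fn = function(b) -log_posterior_expreg(b, y, X, pm, ps),
               gr = function(b) -grad_log_posterior_expreg(b, y, X, pm, ps),
               method = "BFGS", hessian = TRUE)
  Sigma <- tryCatch(solve(opt$hessian) * 2.38^2 / p,
                    error = function(e) diag(1 / p, p))
  L <- tryCatch(chol(Sigma), error = function(e) chol(diag(1 / p, p)))

  res <- rwm_expreg_cpp(as.numeric(y), X, opt$par, L, pm, ps,
                        as.integer(n_iter), as.integer(burn_in),
                        as.integer(thin), target_acc)
  if (is.finite(res$acceptance_rate) && res$acceptance_rate < 0.02) {
    stop("Metropolis chain failed to mix (acceptance rate ",
         format(res$acceptance_rate, digits = 3),
         " after adaptation); inspect the model or priors", call. = FALSE)
  }
  draws <- res$draws
  colnames(draws) <- colnames(X)
  structure(
    list(draws = draws, acceptance_rate = res$acceptance_rate,
         map = stats::setNames(opt$par, colnames(X)),
         n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
         formula = formula, terms = attr(mf, "terms"), y = y, X = X,
         prior_mean = pm, prior_sd = ps),
    class = "exp_reg_fit"
  )
}

#' @export
print.exp_reg_fit <- function(x, ...) {
  cat("Bayesian exponential regression (random-walk Metropolis)\n")
  cat(sprintf("  %d retained draws (n_iter = %g, burn-in = %g, thin = %d), acceptance %.2f\n",
              nrow(x$draws), x$n_iter, x$burn_in, x$thin,
              x$acceptance_rate))
  cat("  posterior means:\n")
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

#' Posterior predictive draws for a new covariate row
#'
#' One exponential draw per retained posterior draw, with rate
#' exp(-x_new' beta). The sample mean estimates the predictive mean and
#' sample quantiles give equal-tailed predictive intervals.
#'
#' @param fit an [fit_exp_reg()] result.
#' @param newdata one-row data frame with the model covariates.
#' @return Numeric vector of predictive response draws, one per retained
#'   posterior draw.
#' @export
predictive_draws <- function(fit, newdata) {
  stopifnot(inherits(fit, "exp_reg_fit"))
  tt <- delete.response(fit$terms)
  x_new <- model.matrix(tt, model.frame(tt, newdata))
  if (nrow(x_new) != 1L) stop_input("newdata must contain exactly one row")
  eta <- drop(fit$draws %*% drop(x_new))
  rexp(length(eta), rate = exp(-eta))
}

#' Root mean squared error of predictive means
#'
#' `rmse()` compares observed responses with the predictive point
#' estimates (the means of the predictive distributions). The method for
#' leave-one-out reports pulls both from the per-observation table.
#'
#' @param object observed responses, or a `loo_report`.
#' @param y_hat predictive means (default method).
#' @param ... unused.
#' @return The root mean squared error.
#' @export
rmse <- function(object, ...) UseMethod("rmse")

#' @rdname rmse
#' @export
rmse.default <- function(object, y_hat, ...) {
  if (length(object) != length(y_hat)) {
    stop_input("observed and predicted vectors must have equal length")
  }
  sqrt(mean((object - y_hat)^2))
}

#' @rdname rmse
#' @export
rmse.loo_report <- function(object, ...) {
  rows <- object$rows
  if (anyNA(rows$y_hat)) {
    stop_input("this report carries no predictive means")
  }
  sqrt(mean((rows$y - rows$y_hat)^2))
}
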