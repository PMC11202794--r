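#' Exponential-Gamma conjugate model
#'
#' Sufficient statistics and hyperparameters for exponential data
#' x | theta ~ Exponential(theta) (mean 1/theta) with a Gamma(a, b) prior
#' on the rate. The posterior is Gamma(a + n, b + sum_x) and the
#' predictive distribution of a new observation is Lomax with density
#' (a+n) (b+S)^(a+n) / (y + b + S)^(a+n+1).
#'
#' @param x optional data vector (positive); alternatively give `n` and
#'   `sum_x` directly.
#' @param a,b positive Gamma prior shape and rate. The default 0.01
#'   (i.e. 1/100) is the diffuse prior used in the worked examples.
#' @param n,sum_x sufficient statistics, used when `x` is omitted.
#' @return An object of class `exp_gamma_model`.
#' @examples
#' m <- exp_gamma_model(a = 1, b = 1, n = 0, sum_x = 0)
#' exp_equal_tailed_ci(m, gamma = 0.5)  # [1/3, 3]
#' @export
exp_gamma_model <- function(x = NULL, a = 0.01, b = 0.01, n = NULL,
                            sum_x = NULL) {
  if (a <= 0 || b <= 0) stop_input("prior hyperparameters must be positive")
  if (!is.null(x)) {
    if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
      stop_input("x must be positive")
    }
    n <- length(x)
    sum_x <- sum(x)
  } else if (is.null(n) || is.null(sum_x)) {
    stop_input("supply either x or both n and sum_x")
  }
  if (n < 0 || sum_x < 0) stop_input("sufficient statistics must be >= 0")
  structure(list(a = a, b = b, n = n, sum_x = sum_x),
            class = "exp_gamma_model")
}

#' @export
print.exp_gamma_model <- function(x, ...) {
  cat(sprintf("Exponential-Gamma model: posterior theta ~ Gamma(%g, %g)  (n = %g)\n",
              x$a + x$n, x$b + x$sum_x, x$n))
  invisible(x)
}

#' Exponential-Gamma predictive density, cdf, quantile and sampler
#'
#' Closed-form predictive (Lomax) machinery for [exp_gamma_model()]:
#' density, cumulative distribution, quantile
#' y_q = (b + S) * ((1-q)^(-1/(a+n)) - 1), and a two-stage sampler that
#' draws theta from the Gamma posterior and then y ~ Exponential(theta).
#'
#' @param y value(s), > 0 for positive density.
#' @param model an [exp_gamma_model()].
#' @param q probability (or probabilities) in (0, 1).
#' @param J number of predictive draws.
#' @return Density, probability, quantile, or sample values.
#' @name exp_gamma_predictive
NULL

#' @rdname exp_gamma_predictive
#' @export
exp_predictive_density <- function(y, model) {
  stopifnot(inherits(model, "exp_gamma_model"))
  shape <- model$a + model$n
  scale <- model$b + model$sum_x
  out <- numeric(length(y))
  pos <- !is.na(y) & y >= 0
  out[pos] <- exp(log(shape) + shape * log(scale) -
                    (shape + 1) * log(y[pos] + scale))
  out[is.na(y)] <- NA_real_
  out
}

#' @rdname exp_gamma_predictive
#' @export
exp_predictive_cdf <- function(y, model) {
  stopifnot(inherits(model, "exp_gamma_model"))
  shape <- model$a + model$n
  scale <- model$b + model$sum_x
  out <- numeric(length(y))
  pos <- !is.na(y) & y > 0
  out[pos] <- -expm1(shape * (log(scale) - log(y[pos] + scale)))
  out[is.na(y)] <- NA_real_
  out
}

#' @rdname exp_gamma_predictive
#' @export
exp_predictive_quantile <- function(q, model) {
  stopifnot(inherits(model, "exp_gamma_model"))
  if (any(q <= 0 | q >= 1)) stop_input("q must lie strictly inside (0, 1)")
  shape <- model$a + model$n
  scale <- model$b + model$sum_x
  scale * ((1 - q)^(-1 / shape) - 1)
}

#' @rdname exp_gamma_predictive
#' @export
exp_predictive_sample <- function(J, model) {
  stopifnot(inherits(model, "exp_gamma_model"))
  theta <- stats::rgamma(J, shape = model$a + model$n,
                         rate = model$b + model$sum_x)
  rexp(J, rate = theta)
}

#' Equal-tailed predictive interval, Exponential-Gamma model
#'
#' The gamma x 100\% equal-tailed credible interval for a new
#' observation, with endpoints at the (1-gamma)/2 and (1+gamma)/2
#' predictive quantiles. The predictive distribution is continuous, so
#' the realized credibility equals the nominal level.
#'
#' @param model an [exp_gamma_model()].
#' @param gamma credible level in (0, 1).
#' @return A [predictive_interval()].
#' @export
exp_equal_tailed_ci <- function(model, gamma = 0.5) {
  if (gamma <= 0 || gamma >= 1) stop_input("gamma must lie in (0, 1)")
  qs <- exp_predictive_quantile(c((1 - gamma) / 2, (1 + gamma) / 2), model)
  predictive_interval(qs[1], qs[2], credibility = gamma,
                      kind = "equal_tailed")
}

#' Poisson-Gamma conjugate model
#'
#' Sufficient statistics and hyperparameters for count data
#' x | theta ~ Poisson(theta) with a Gamma(a, b) prior on the mean. The
#' posterior is Gamma(A, B) with A = a + sum_x and B = b + n, and the
#' predictive distribution of a new count is Gamma-Poisson (negative
#' binomial) with parameters (A, B).
#'
#' @param x optional vector of non-negative integer counts; alternatively
#'   give `n` and `sum_x`.
#' @param a,b positive Gamma prior shape and rate (default the diffuse
#'   1/100).
#' @param n,sum_x sufficient statistics, used when `x` is omitted.
#' @return An object of class `pois_gamma_model` with fields `A`, `B`.
#' @examples
#' m <- pois_gamma_model(n = 30, sum_x = 501.99, a = 0.01, b = 0.01)
#' pois_equal_tailed_limits(m, gamma = 0.5)
#' @export
pois_gamma_model <- function(x = NULL, a = 0.01, b = 0.01, n = NULL,
                             sum_x = NULL) {
  if (a <= 0 || b <= 0) stop_input("prior hyperparameters must be positive")
  if (!is.null(x)) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != round(x))) {
      stop_input("x must be non-negative integer counts")
    }
    n <- length(x)
    sum_x <- sum(x)
  } else if (is.null(n) || is.null(sum_x)) {
    stop_input("supply either x or both n and sum_x")
  }
  structure(list(a = a, b = b, n = n, sum_x = sum_x,
                 A = a + sum_x, B = b + n),
            class = "pois_gamma_model")
}

#' @export
print.pois_gamma_model <- function(x, ...) {
  cat(sprintf("Poisson-Gamma model: predictive Y ~ Gamma-Poisson(A = %g, B = %g)\n",
              x$A, x$B))
  invisible(x)
}

#' Gamma-Poisson predictive pmf and cdf
#'
#' The predictive probability mass function of a new count under the
#' Poisson-Gamma model,
#' f(y) = Gamma(A + y) / (Gamma(A) y!) * B^A / (B + 1)^(A + y),
#' evaluated in log space, and its cumulative distribution computed by a
#' log-space recurrence f(y+1)/f(y) = (A + y) / ((y + 1)(B + 1)) with
#' summation truncated once the accumulated mass reaches 1 - 1e-12.
#'
#' @param y non-negative integer count(s).
#' @param model a [pois_gamma_model()].
#' @return Probabilities.
#' @name pois_gamma_predictive
NULL

#' @rdname pois_gamma_predictive
#' @export
pois_predictive_pmf <- function(y, model) {
  stopifnot(inherits(model, "pois_gamma_model"))
  if (any(!is.na(y) & (y < 0 | y != round(y)))) {
    stop_input("y must be non-negative integers")
  }
  A <- model$A
  B <- model$B
  exp(lgamma(A + y) - lgamma(A) - lgamma(y + 1) +
        A * log(B) - (A + y) * log(B + 1))
}

# pmf values f(0..y_max) by the log-space recurrence
pois_pmf_upto <- function(model, y_max) {
  A <- model$A
  B <- model$B
  lp <- numeric(y_max + 1)
  lp[1] <- A * (log(B) - log(B + 1))
  if (y_max > 0) {
    y <- 0:(y_max - 1)
    lp[-1] <- lp[1] + cumsum(log(A + y) - log(y + 1) - log(B + 1))
  }
  exp(lp)
}

#' @rdname pois_gamma_predictive
#' @export
pois_predictive_cdf <- function(y, model) {
  stopifnot(inherits(model, "pois_gamma_model"))
  y <- floor(y)
  out <- numeric(length(y))
  ok <- !is.na(y) & y >= 0
  if (any(ok)) {
    cum <- cumsum(pois_pmf_upto(model, max(y[ok])))
    out[ok] <- pmin(cum[y[ok] + 1], 1)
  }
  out[is.na(y)] <- NA_real_
  out
}

#' Equal-tailed predictive interval, Poisson-Gamma model
#'
#' Integer interval limits L1 = sup\{y : F(y) <= (1 - gamma)/2\} and
#' L2 = inf\{y : F(y) >= (1 + gamma)/2\} for the Gamma-Poisson
#' predictive cdf F, splitting the excluded mass 1 - gamma evenly
#' between the tails. When no y satisfies the L1 condition (the sup runs
#' over an empty set), L1 = 0 so that the interval stays inside the
#' support. Because the predictive is discrete the realized credibility
#' F(L2) - F(L1 - 1) is at least gamma.
#'
#' @param model a [pois_gamma_model()].
#' @param gamma credible level in (0, 1).
#' @return A [predictive_interval()] with integer limits and the realized
#'   credibility.
#' @export
pois_equal_tailed_limits <- function(model, gamma = 0.5) {
  stopifnot(inherits(model, "pois_gamma_model"))
  if (gamma <= 0 || gamma >= 1) stop_input("gamma must lie in (0, 1)")
  mean_y <- model$A / model$B
  sd_y <- sqrt(model$A * (model$B + 1)) / model$B
  p_lo <- (1 - gamma) / 2
  p_hi <- (1 + gamma) / 2
  y_max <- max(20, ceiling(mean_y + 20 * sd_y))
  cum <- cumsum(pois_pmf_upto(model, y_max))
  while (cum[length(cum)] < p_hi) {
    y_max <- y_max * 2
    cum <- cumsum(pois_pmf_upto(model, y_max))
  }
  below <- which(cum <= p_lo)  # index i corresponds to y = i - 1
  L1 <- if (length(below)) max(below) - 1L else 0L
  L2 <- min(which(cum >= p_hi)) - 1L
  realized <- cum[L2 + 1] - if (L1 > 0) cum[L1] else 0
  predictive_interval(L1, L2, credibility = gamma,
                      realized_credibility = realized,
                      kind = "equal_tailed")
}

#' HPD interval from predictive draws
#'
#' Empirical highest-density interval: among all windows of
#' ceiling(gamma * J) consecutive order statistics, the shortest
#' (left-most on ties, for deterministic output).
#'
#' @param draws sample from the predictive distribution (>= 100 draws).
#' @param gamma credible level in (0, 1).
#' @return A [predictive_interval()] of kind `"hpd"`.
#' @export
hpd_from_samples <- function(draws, gamma = 0.5) {
  if (length(draws) < 100L) stop_input("at least 100 draws are required")
  if (gamma <= 0 || gamma >= 1) stop_input("gamma must lie in (0, 1)")
  J <- length(draws)
  m <- ceiling(gamma * J)
  s <- sort(draws)
  widths <- s[m:J] - s[1:(J - m + 1)]
  i <- which.min(widths)  # which.min returns the first (left-most) minimum
  predictive_interval(s[i], s[i + m - 1], credibility = gamma, kind = "hpd")
}
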