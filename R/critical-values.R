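#' Exact critical value for the accuracy measure
#'
#' Calibrates the rejection threshold for |Delta| = |kappa - gamma| at
#' level alpha and sample size n against the FBST: the e-value for
#' H: kappa = gamma is computed at every achievable count u in 0..n, and
#' the threshold is the midpoint between the largest non-rejected and the
#' smallest rejected achievable |Delta| on each side of gamma. Downstream
#' the model is rejected when |Delta_obs| exceeds this threshold, which
#' reproduces the FBST decision exactly on the achievable grid.
#'
#' For gamma = 0.5 the two sides are symmetric and a single threshold is
#' returned; otherwise a named vector with separate `lower` and `upper`
#' thresholds is returned.
#'
#' @param n sample size (>= 2).
#' @param alpha critical level in (0, 1).
#' @param gamma nominal credible level, default 0.5.
#' @param prior Beta prior shapes `c(a1, a2)` for the coverage
#'   proportion, default the uniform Beta(1, 1) used in the bundled
#'   calibration tables.
#' @param rounded round the threshold(s) half-up to 3 decimals for table
#'   display; `FALSE` returns full precision.
#' @return Threshold(s) for |Delta_obs|.
#' @examples
#' delta_critical_exact(30, alpha = 0.05)  # 0.183
#' @export
delta_critical_exact <- function(n, alpha = 0.05, gamma = 0.5,
                                 prior = c(1, 1), rounded = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop_input("n must be an integer >= 2")
  }
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must lie in (0, 1)")
  if (gamma <= 0 || gamma >= 1) stop_input("gamma must lie in (0, 1)")

  side_threshold <- function(us) {
    prev_d <- NULL
    for (u in us) {
      ev <- evalue_analytic(prior[1] + u, prior[2] + n - u, gamma)
      d <- abs(u / n - gamma)
      if (ev < alpha) {
        if (is.null(prev_d)) return(d)  # even the innermost count rejects
        return((prev_d + d) / 2)
      }
      prev_d <- d
    }
    warning("no achievable count rejects at alpha = ", alpha,
            "; returning the maximal achievable |Delta| boundary")
    prev_d
  }

  lower <- side_threshold(floor(n * gamma):0)
  if (isTRUE(all.equal(gamma, 0.5))) {
    out <- lower
  } else {
    upper <- side_threshold(ceiling(n * gamma):n)
    out <- c(lower = lower, upper = upper)
  }
  if (rounded) round_half_up(out, 3) else out
}

# beta1 coefficients of the large-n approximation beta1/sqrt(n), from the
# bundled calibration at gamma = 0.5, Beta(1,1) prior
.approx_beta1 <- c("0.01" = 1.261, "0.05" = 0.966, "0.1" = 0.812,
                   "0.2" = 0.633)

#' Large-sample approximation to the critical value
#'
#' Returns beta1/sqrt(n), the fitted approximation to the exact critical
#' value, intended for n > 40. Coefficients for alpha in
#' {0.01, 0.05, 0.10, 0.20} are bundled (1.261, 0.966, 0.812, 0.633);
#' other levels require a [fit_beta1()] calibration.
#'
#' @param n sample size; a warning is issued for n <= 40 where the exact
#'   table should be used instead.
#' @param alpha critical level; must be one of the bundled levels unless
#'   `fit` is supplied.
#' @param fit optional `calibration_fit` from [fit_beta1()].
#' @return The approximate threshold beta1/sqrt(n).
#' @examples
#' delta_critical_approx(100, 0.05)  # 0.0966
#' @export
delta_critical_approx <- function(n, alpha = 0.05, fit = NULL) {
  if (n <= 40) {
    warning("the beta1/sqrt(n) approximation is calibrated for n > 40; ",
            "use delta_critical_exact() for small samples")
  }
  if (!is.null(fit)) {
    if (!inherits(fit, "calibration_fit")) {
      stop_input("fit must be a calibration_fit object")
    }
    b1 <- fit$beta1
  } else {
    key <- format(alpha, trim = TRUE)
    if (!key %in% names(.approx_beta1)) {
      stop_input("no bundled coefficient for alpha = ", alpha,
                 "; supply a calibration fit from fit_beta1()")
    }
    b1 <- .approx_beta1[[key]]
  }
  b1 / sqrt(n)
}

#' Calibrate the large-sample coefficient beta1
#'
#' Generates the exact critical errors xi = |Delta_critical| over a grid
#' of sample sizes and fits the no-intercept least-squares model
#' xi = beta1 / sqrt(n), using the closed form
#' beta1 = sum(xi_i / sqrt(n_i)) / sum(1 / n_i).
#'
#' @param alpha critical level.
#' @param n_grid integer sample sizes, within 10..500 (the range the
#'   bundled coefficients were calibrated on); at least 5 points.
#' @param gamma nominal credible level, default 0.5.
#' @param prior Beta prior shapes, default Beta(1, 1).
#' @return An object of class `calibration_fit` with fields `alpha`,
#'   `beta1`, `n_grid`, `xi` (the critical errors), `fitted`,
#'   `residuals`.
#' @export
fit_beta1 <- function(alpha = 0.05, n_grid = 10:500, gamma = 0.5,
                      prior = c(1, 1)) {
  if (length(n_grid) < 5L) stop_input("n_grid needs at least 5 points")
  if (any(n_grid < 10 | n_grid > 500)) {
    stop_input("n_grid must lie within 10..500")
  }
  xi <- vapply(n_grid, function(n) {
    delta_critical_exact(n, alpha, gamma, prior)[1]
  }, numeric(1))
  beta1 <- sum(xi / sqrt(n_grid)) / sum(1 / n_grid)
  fitted <- beta1 / sqrt(n_grid)
  structure(
    list(alpha = alpha, beta1 = beta1, n_grid = n_grid, xi = xi,
         fitted = fitted, residuals = xi - fitted),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Critical-error calibration: xi = %.4f / sqrt(n)  (alpha = %g, %d grid points)\n",
              x$beta1, x$alpha, length(x$n_grid)))
  invisible(x)
}

#' Table of exact critical values
#'
#' Regenerates the reference table of critical values of Delta for
#' gamma = 0.5, by sample size and level, rounded half-up to 3 decimals.
#'
#' @param n_grid sample sizes (default 10..40, the small-sample range
#'   where the large-n approximation is not yet reliable).
#' @param alphas critical levels (default 0.01, 0.05, 0.10, 0.20).
#' @param gamma,prior passed to [delta_critical_exact()].
#' @return A data frame with column `n` and one column per alpha.
#' @export
critical_value_table <- function(n_grid = 10:40,
                                 alphas = c(0.01, 0.05, 0.10, 0.20),
                                 gamma = 0.5, prior = c(1, 1)) {
  vals <- sapply(alphas, function(a) {
    vapply(n_grid, function(n) {
      delta_critical_exact(n, a, gamma, prior, rounded = TRUE)[1]
    }, numeric(1))
  })
  out <- data.frame(n = n_grid, vals)
  names(out) <- c("n", paste0("alpha_", format(alphas, trim = TRUE)))
  out
}
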