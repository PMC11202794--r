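#' Beta posterior for the proportion of correct predictions
#'
#' Updates a Beta(a1, a2) prior on the leave-one-out coverage proportion
#' kappa with a vector of binary coverage indicators (1 = the held-out
#' observation fell inside its predictive interval). The posterior is
#' Beta(A1, A2) with A1 = a1 + sum(u) and A2 = a2 + n - sum(u).
#'
#' @param u binary vector of coverage indicators (entries 0 or 1). May be
#'   omitted when `n` and `u_sum` are given directly.
#' @param a1,a2 positive Beta prior shapes. The default Beta(1, 1) is the
#'   uniform prior used throughout the critical-value calibration.
#' @param n,u_sum alternative input: the sample size and the number of
#'   correct predictions, instead of the full indicator vector.
#' @return An object of class `beta_posterior` with fields `a1`, `a2`,
#'   `n`, `u_sum`, `A1`, `A2`.
#' @examples
#' beta_posterior(n = 100, u_sum = 47)
#' beta_posterior(u = c(1, 0, 1, 1))
#' @export
beta_posterior <- function(u = NULL, a1 = 1, a2 = 1, n = NULL, u_sum = NULL) {
  if (!is.numeric(a1) || !is.numeric(a2) || length(a1) != 1L ||
      length(a2) != 1L || !is.finite(a1) || !is.finite(a2) ||
      a1 <= 0 || a2 <= 0) {
    stop_input("prior shapes a1, a2 must be positive finite scalars")
  }
  if (is.null(u)) {
    if (is.null(n) || is.null(u_sum)) {
      stop_input("supply either the indicator vector u or both n and u_sum")
    }
    if (n < 1 || n != round(n)) stop_input("n must be a positive integer")
    if (u_sum < 0 || u_sum > n || u_sum != round(u_sum)) {
      stop_input("u_sum must be an integer in 0..n")
    }
  } else {
    if (length(u) < 1L) stop_input("u must be non-empty")
    if (!is.numeric(u) || anyNA(u) || !all(u %in% c(0, 1))) {
      stop_input("u must contain only 0/1 entries")
    }
    n <- length(u)
    u_sum <- sum(u)
  }
  structure(
    list(a1 = a1, a2 = a2, n = as.integer(n), u_sum = as.integer(u_sum),
         A1 = a1 + u_sum, A2 = a2 + n - u_sum),
    class = "beta_posterior"
  )
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta posterior for coverage proportion: Beta(%g, %g)\n",
              x$A1, x$A2))
  cat(sprintf("  n = %d, correct predictions = %d, prior Beta(%g, %g)\n",
              x$n, x$u_sum, x$a1, x$a2))
  invisible(x)
}

#' FBST evidence value for H: kappa = gamma0
#'
#' Computes the Full Bayesian Significance Test (FBST) e-value for the
#' point hypothesis that the coverage proportion kappa equals `gamma0`,
#' under a Beta(A1, A2) posterior. The e-value is the posterior
#' probability of the set of kappa values whose density does not exceed
#' the density at `gamma0`; small e-values discredit the hypothesis.
#'
#' Two routes are available. `method = "mc"` draws M values from the
#' posterior and counts the fraction with density less than or equal to
#' the density at `gamma0` (ties count). `method = "analytic"` resolves
#' the density level set exactly: for a unimodal posterior it is the
#' union of two tails whose inner endpoints share the density value at
#' `gamma0`, with the non-trivial endpoint found by bracketed
#' root-finding on the log density; monotone and U-shaped posteriors
#' (shape parameters at or below 1) are classified first and handled by
#' direct tail masses.
#'
#' @param post a [beta_posterior()] object.
#' @param gamma0 tested null value, in (0, 1).
#' @param method `"analytic"` (deterministic, default) or `"mc"`
#'   (Monte Carlo).
#' @param M number of Monte Carlo replicates for `method = "mc"`.
#' @param seed optional integer seed for the Monte Carlo route.
#' @return An object of class `fbst_result` with fields `e_value`,
#'   `gamma0`, `method`, `M` (Monte Carlo only), `seed`, `posterior`.
#' @examples
#' post <- beta_posterior(n = 33, u_sum = 11)
#' e_value(post, gamma0 = 0.5)
#' @export
e_value <- function(post, gamma0 = 0.5, method = c("analytic", "mc"),
                    M = 1e6, seed = NULL) {
  if (!inherits(post, "beta_posterior")) {
    stop_input("post must be a beta_posterior object")
  }
  if (!is.numeric(gamma0) || length(gamma0) != 1L || !is.finite(gamma0) ||
      gamma0 <= 0 || gamma0 >= 1) {
    stop_input("gamma0 must lie strictly inside (0, 1)")
  }
  method <- match.arg(method)
  if (method == "mc") {
    if (M < 1) stop_input("M must be at least 1")
    if (!is.null(seed)) set.seed(seed)
    kappa <- rbeta(M, post$A1, post$A2)
    lf <- dbeta(kappa, post$A1, post$A2, log = TRUE)
    lf_h <- dbeta(gamma0, post$A1, post$A2, log = TRUE)
    ev <- mean(lf <= lf_h)
  } else {
    ev <- evalue_analytic(post$A1, post$A2, gamma0)
  }
  structure(
    list(e_value = ev, gamma0 = gamma0, method = method,
         M = if (method == "mc") M else NULL, seed = seed,
         posterior = post),
    class = "fbst_result"
  )
}

# Exact e-value: posterior mass of {kappa : f(kappa) <= f(gamma0)} under
# Beta(A1, A2), by density-shape classification and bracketed root-finding.
evalue_analytic <- function(A1, A2, gamma0) {
  lf <- function(k) dbeta(k, A1, A2, log = TRUE)
  eps <- 1e-15
  find_other <- function(lower, upper, target) {
    fl <- lf(lower) - target
    fu <- lf(upper) - target
    if (fl > 0 && fu > 0) {
      # the density exceeds the level everywhere inside the bracket: the
      # root lies beyond the bracket edge, where the remaining tail mass
      # is below machine precision -- clamp to the edge
      return(if (fl < fu) lower else upper)
    }
    if (is.nan(fl) || is.nan(fu) || fl * fu > 0) {
      stop("level-set root bracketing failed: f(", format(lower), ") - f0 = ",
           format(fl), ", f(", format(upper), ") - f0 = ", format(fu),
           " for Beta(", format(A1), ", ", format(A2), ") at gamma0 = ",
           format(gamma0), call. = FALSE)
    }
    uniroot(function(k) lf(k) - target, c(lower, upper), tol = 1e-12)$root
  }
  if (A1 > 1 && A2 > 1) {
    mode <- (A1 - 1) / (A1 + A2 - 2)
    target <- lf(gamma0)
    if (lf(mode) - target < 1e-10) return(1)
    if (gamma0 < mode) {
      hi <- find_other(mode, 1 - eps, target)
      lo <- gamma0
    } else {
      lo <- find_other(eps, mode, target)
      hi <- gamma0
    }
    pbeta(lo, A1, A2) + pbeta(hi, A1, A2, lower.tail = FALSE)
  } else if (A1 <= 1 && A2 <= 1) {
    if (A1 == 1 && A2 == 1) return(1)  # flat density: whole support
    # U-shaped: the level set is an interval around the antimode
    anti <- (A1 - 1) / (A1 + A2 - 2)
    target <- lf(gamma0)
    if (lf(anti) - target > -1e-10 && gamma0 >= anti - 1e-12 &&
        gamma0 <= anti + 1e-12) {
      return(0)
    }
    if (gamma0 < anti) {
      hi <- find_other(anti, 1 - eps, target)
      lo <- gamma0
    } else {
      lo <- find_other(eps, anti, target)
      hi <- gamma0
    }
    pbeta(hi, A1, A2) - pbeta(lo, A1, A2)
  } else if (A1 <= 1) {
    # strictly decreasing density: level set is [gamma0, 1]
    pbeta(gamma0, A1, A2, lower.tail = FALSE)
  } else {
    # strictly increasing density: level set is [0, gamma0]
    pbeta(gamma0, A1, A2)
  }
}

#' @export
print.fbst_result <- function(x, ...) {
  cat(sprintf("FBST e-value = %.4f for H: kappa = %g (%s%s)\n",
              x$e_value, x$gamma0, x$method,
              if (x$method == "mc") sprintf(", M = %g", x$M) else ""))
  invisible(x)
}

#' FBST decision rule
#'
#' Rejects the hypothesis kappa = gamma0 when the e-value falls strictly
#' below the critical level alpha.
#'
#' @param result an [e_value()] result, or a bare numeric e-value.
#' @param alpha critical level in (0, 1).
#' @return `"reject"` or `"not_reject"`.
#' @export
fbst_decision <- function(result, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_input("alpha must lie strictly inside (0, 1)")
  }
  ev <- if (inherits(result, "fbst_result")) result$e_value else result
  if (!is.numeric(ev) || length(ev) != 1L || ev < 0 || ev > 1) {
    stop_input("e-value must be a single number in [0, 1]")
  }
  if (ev < alpha) "reject" else "not_reject"
}
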