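#' Predictive credible interval
#'
#' Container for one held-out observation's predictive credible interval.
#' For a continuous predictive distribution the realized credibility
#' equals the nominal level; for a discrete predictive the interval
#' covers at least the nominal mass, and the realized value is recorded
#' so that the average credibility can replace gamma in the FBST.
#'
#' @param lower,upper interval endpoints, in response units.
#' @param credibility nominal credible level gamma in (0, 1).
#' @param realized_credibility actual probability mass covered; defaults
#'   to the nominal level.
#' @param kind `"equal_tailed"` or `"hpd"`.
#' @return An object of class `predictive_interval`.
#' @export
predictive_interval <- function(lower, upper, credibility,
                                realized_credibility = credibility,
                                kind = c("equal_tailed", "hpd")) {
  kind <- match.arg(kind)
  if (!is.numeric(lower) || !is.numeric(upper) || length(lower) != 1L ||
      length(upper) != 1L || is.na(lower) || is.na(upper) || lower > upper) {
    stop_input("interval requires numeric lower <= upper")
  }
  if (credibility <= 0 || credibility >= 1) {
    stop_input("credibility must lie strictly inside (0, 1)")
  }
  if (realized_credibility < credibility - 1e-9) {
    stop_input("realized credibility cannot fall below the nominal level")
  }
  structure(
    list(lower = lower, upper = upper, credibility = credibility,
         realized_credibility = realized_credibility, kind = kind),
    class = "predictive_interval"
  )
}

#' @export
print.predictive_interval <- function(x, ...) {
  cat(sprintf("%g%% %s predictive interval: [%.4g, %.4g]",
              100 * x$credibility,
              if (x$kind == "hpd") "HPD" else "equal-tailed",
              x$lower, x$upper))
  if (abs(x$realized_credibility - x$credibility) > 1e-12) {
    cat(sprintf("  (realized credibility %.3f)", x$realized_credibility))
  }
  cat("\n")
  invisible(x)
}

#' Coverage indicator for a held-out observation
#'
#' Returns 1 when the observed value falls inside the predictive
#' interval (closed on both ends: a value on a boundary counts as
#' covered), 0 otherwise.
#'
#' @param y observed response value.
#' @param ci a [predictive_interval()].
#' @return 0 or 1.
#' @export
coverage_indicator <- function(y, ci) {
  if (!inherits(ci, "predictive_interval")) {
    stop_input("ci must be a predictive_interval")
  }
  as.integer(y >= ci$lower & y <= ci$upper)
}

#' Coverage proportion and accuracy measure
#'
#' Aggregates the binary coverage indicators into the proportion of
#' correct predictions kappa = sum(u)/n and the accuracy measure
#' Delta = kappa - gamma. Delta = 0 indicates calibrated predictive
#' coverage; Delta < 0 flags under-coverage (poor predictive capacity)
#' and Delta > 0 over-wide intervals.
#'
#' @param u binary coverage-indicator vector.
#' @param gamma nominal credible level of the intervals, in (0, 1).
#' @param avg_credibility optional mean realized credibility of the n
#'   intervals (discrete predictive case), carried along for use as the
#'   FBST null value.
#' @return An object of class `coverage_record` with fields `u`, `n`,
#'   `gamma`, `kappa`, `delta`, `avg_credibility`.
#' @examples
#' accuracy_measure(c(rep(1, 11), rep(0, 22)), gamma = 0.5)
#' @export
accuracy_measure <- function(u, gamma, avg_credibility = NULL) {
  if (length(u) < 1L) stop_input("u must be non-empty")
  if (!is.numeric(u) || anyNA(u) || !all(u %in% c(0, 1))) {
    stop_input("u must contain only 0/1 entries")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma >= 1) {
    stop_input("gamma must lie strictly inside (0, 1)")
  }
  n <- length(u)
  kappa <- sum(u) / n
  structure(
    list(u = as.integer(u), n = n, gamma = gamma, kappa = kappa,
         delta = kappa - gamma, avg_credibility = avg_credibility),
    class = "coverage_record"
  )
}

#' @export
print.coverage_record <- function(x, ...) {
  cat(sprintf("Coverage record: n = %d, kappa = %d/%d = %.3f, Delta = %.3f (gamma = %g)\n",
              x$n, sum(x$u), x$n, x$kappa, x$delta, x$gamma))
  if (!is.null(x$avg_credibility)) {
    cat(sprintf("  average realized credibility = %.3f\n", x$avg_credibility))
  }
  invisible(x)
}

#' Average realized credibility of a set of intervals
#'
#' Mean of the realized credibilities across leave-one-out predictive
#' intervals. For a discrete predictive distribution each interval covers
#' at least the nominal mass, so this average (rather than gamma itself)
#' is the natural null value for the FBST.
#'
#' @param cis list of [predictive_interval()] objects.
#' @return The mean realized credibility.
#' @export
average_credibility <- function(cis) {
  if (length(cis) < 1L) stop_input("cis must be non-empty")
  rc <- vapply(cis, function(ci) {
    if (!inherits(ci, "predictive_interval") ||
        is.null(ci$realized_credibility) || is.na(ci$realized_credibility)) {
      stop_input("every interval must carry a realized credibility")
    }
    ci$realized_credibility
  }, numeric(1))
  mean(rc)
}
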