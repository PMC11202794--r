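#' Model factories for the leave-one-out engine
#'
#' [run_loo()] works against any model object implementing two
#' capabilities: `fit_model(model, data)` fits on a data subset and
#' `predict_interval(fitted, newdata, gamma, kind)` returns a
#' [predictive_interval()] for a held-out row (with the predictive mean
#' attached as attribute `y_hat` when available). Three factories are
#' provided: the conjugate Exponential-Gamma and Poisson-Gamma models for
#' univariate data, and the MCMC exponential regression for tabular data
#' with covariates.
#'
#' @param a,b Gamma prior shape and rate for the conjugate models
#'   (default the diffuse 1/100).
#' @param formula model formula for the regression model.
#' @param prior_mean,prior_sd normal prior settings for the regression
#'   coefficients.
#' @param n_iter,burn_in,thin Metropolis chain settings per
#'   leave-one-out fit.
#' @return A model factory object for [run_loo()].
#' @name loo_models
NULL

#' @rdname loo_models
#' @export
exp_conjugate_model <- function(a = 0.01, b = 0.01) {
  structure(list(a = a, b = b), class = c("exp_conjugate_spec", "loo_model"))
}

#' @rdname loo_models
#' @export
pois_conjugate_model <- function(a = 0.01, b = 0.01) {
  structure(list(a = a, b = b), class = c("pois_conjugate_spec", "loo_model"))
}

#' @rdname loo_models
#' @export
exp_reg_model <- function(formula, prior_mean = 0, prior_sd = 100,
                          n_iter = 50000, burn_in = 5000, thin = 5) {
  structure(list(formula = formula, prior_mean = prior_mean,
                 prior_sd = prior_sd, n_iter = n_iter, burn_in = burn_in,
                 thin = thin),
            class = c("exp_reg_spec", "loo_model"))
}

#' @rdname loo_models
#' @param model a model factory.
#' @param data the data subset to fit on.
#' @export
fit_model <- function(model, data) UseMethod("fit_model")

#' @export
fit_model.exp_conjugate_spec <- function(model, data) {
  exp_gamma_model(x = as_response_vector(data), a = model$a, b = model$b)
}

#' @export
fit_model.pois_conjugate_spec <- function(model, data) {
  pois_gamma_model(x = as_response_vector(data), a = model$a, b = model$b)
}

#' @export
fit_model.exp_reg_spec <- function(model, data) {
  fit_exp_reg(model$formula, data, prior_mean = model$prior_mean,
              prior_sd = model$prior_sd, n_iter = model$n_iter,
              burn_in = model$burn_in, thin = model$thin)
}

#' @rdname loo_models
#' @param fitted a fitted model from `fit_model()`.
#' @param newdata the held-out row (ignored by the exchangeable
#'   conjugate models).
#' @param gamma credible level.
#' @param kind interval type, `"equal_tailed"` or `"hpd"`.
#' @export
predict_interval <- function(fitted, newdata, gamma = 0.5,
                             kind = "equal_tailed") {
  UseMethod("predict_interval")
}

#' @export
predict_interval.exp_gamma_model <- function(fitted, newdata, gamma = 0.5,
                                             kind = "equal_tailed") {
  if (kind == "hpd") {
    ci <- hpd_from_samples(exp_predictive_sample(1e4, fitted), gamma)
  } else {
    ci <- exp_equal_tailed_ci(fitted, gamma)
  }
  shape <- fitted$a + fitted$n
  attr(ci, "y_hat") <- if (shape > 1) {
    (fitted$b + fitted$sum_x) / (shape - 1)
  } else {
    NA_real_  # Lomax mean undefined for shape <= 1
  }
  ci
}

#' @export
predict_interval.pois_gamma_model <- function(fitted, newdata, gamma = 0.5,
                                              kind = "equal_tailed") {
  if (kind == "hpd") {
    stop_input("HPD intervals are not provided for the discrete predictive")
  }
  ci <- pois_equal_tailed_limits(fitted, gamma)
  attr(ci, "y_hat") <- fitted$A / fitted$B
  ci
}

#' @export
predict_interval.exp_reg_fit <- function(fitted, newdata, gamma = 0.5,
                                         kind = "equal_tailed") {
  draws <- predictive_draws(fitted, newdata)
  if (kind == "hpd") {
    ci <- hpd_from_samples(draws, gamma)
  } else {
    qs <- unname(quantile(draws, c((1 - gamma) / 2, (1 + gamma) / 2)))
    ci <- predictive_interval(qs[1], qs[2], credibility = gamma,
                              kind = "equal_tailed")
  }
  attr(ci, "y_hat") <- mean(draws)
  ci
}

# observed responses for each model type
response_values <- function(model, data) UseMethod("response_values")

#' @export
response_values.exp_reg_spec <- function(model, data) {
  model.response(model.frame(model$formula, data))
}

#' @export
response_values.loo_model <- function(model, data) as_response_vector(data)

as_response_vector <- function(data) {
  if (is.data.frame(data)) {
    if (ncol(data) != 1L) {
      stop_input("univariate models expect a vector or one-column data frame")
    }
    data <- data[[1]]
  }
  as.numeric(data)
}

subset_rows <- function(data, idx) {
  if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
}

#' Leave-one-out predictive coverage assessment
#'
#' Runs the full accuracy pipeline: each observation is removed in turn,
#' the model is refitted on the remainder, a predictive credible interval
#' for the held-out observation is built, and coverage is scored. The
#' coverage proportion kappa and accuracy measure Delta = kappa - gamma
#' are then tested two ways: the FBST e-value for H: kappa = gamma
#' (rejecting when e-value < alpha) and the calibrated threshold rule
#' (rejecting when |Delta| exceeds the exact critical value for this n
#' and alpha).
#'
#' Conjugate model fits reuse sufficient statistics, so each
#' leave-one-out refit is a subtraction rather than a loop. For MCMC
#' models a fresh seed per leave-one-out fit is derived deterministically
#' from the master seed, keeping results reproducible without
#' correlating chains across fits.
#'
#' @param model a model factory (see [loo_models]).
#' @param data the full dataset: a numeric vector for the conjugate
#'   models, a data frame for the regression model.
#' @param gamma nominal credible level of the intervals.
#' @param alpha critical level for both decision rules.
#' @param kind interval type, `"equal_tailed"` (the calibrated default)
#'   or `"hpd"`.
#' @param use_avg_credibility replace gamma with the mean realized
#'   credibility of the n intervals as the FBST null value (discrete
#'   predictive distributions).
#' @param seed optional master seed.
#' @return An object of class `loo_report`: per-observation table
#'   `rows` (interval, predictive mean, coverage), the `record`
#'   ([accuracy_measure()]), the FBST `e_value`, the `delta_critical`
#'   threshold and both `decisions`.
#' @examples
#' set.seed(1)
#' x <- rexp(40, rate = 0.2)
#' run_loo(exp_conjugate_model(), x, gamma = 0.5, alpha = 0.05)
#' @export
run_loo <- function(model, data, gamma = 0.5, alpha = 0.05,
                    kind = c("equal_tailed", "hpd"),
                    use_avg_credibility = FALSE, seed = NULL) {
  kind <- match.arg(kind)
  if (!inherits(model, "loo_model")) {
    stop_input("model must be a loo model factory (see ?loo_models)")
  }
  n <- NROW(data)
  if (n < 2) stop_input("at least 2 observations are required")
  y <- response_values(model, data)

  row_seeds <- NULL
  if (!is.null(seed)) {
    set.seed(seed)
    row_seeds <- sample.int(.Machine$integer.max - 1L, n)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.null(row_seeds)) set.seed(row_seeds[i])
    fitted <- tryCatch(
      fit_model(model, subset_rows(data, -i)),
      error = function(e) {
        stop("leave-one-out fit failed for observation ", i, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    ci <- predict_interval(fitted, subset_rows(data, i), gamma, kind)
    rows[[i]] <- data.frame(
      index = i, y = y[i],
      y_hat = if (is.null(attr(ci, "y_hat"))) NA_real_ else attr(ci, "y_hat"),
      lower = ci$lower, upper = ci$upper,
      realized_credibility = ci$realized_credibility,
      covered = coverage_indicator(y[i], ci)
    )
  }
  rows <- do.call(rbind, rows)

  avg_cred <- mean(rows$realized_credibility)
  record <- accuracy_measure(rows$covered, gamma,
                             avg_credibility = avg_cred)
  dec <- decide(record, alpha = alpha,
                use_avg_credibility = use_avg_credibility)
  structure(
    list(rows = rows, record = record, e_value = dec$e_value,
         delta_critical = dec$delta_critical, decisions = dec$decisions,
         gamma = gamma, alpha = alpha, kind = kind, seed = seed),
    class = "loo_report"
  )
}

#' Apply both decision rules to a coverage record
#'
#' Computes the FBST e-value (analytic route) for H: kappa = gamma --
#' or H: kappa = kappa*, the average realized credibility, when
#' `use_avg_credibility` is set -- together with the exact critical
#' threshold for |Delta|, and reports both decisions.
#'
#' @param record a [accuracy_measure()] result.
#' @param alpha critical level.
#' @param use_avg_credibility use the record's average realized
#'   credibility as the FBST null value.
#' @param prior Beta prior shapes for the coverage proportion.
#' @return A list with `e_value` (an `fbst_result`), `delta_critical`,
#'   and `decisions` (list with elements `fbst` and `delta_rule`, each
#'   `"reject"` or `"not_reject"`).
#' @export
decide <- function(record, alpha = 0.05, use_avg_credibility = FALSE,
                   prior = c(1, 1)) {
  if (!inherits(record, "coverage_record")) {
    stop_input("record must be a coverage_record")
  }
  gamma0 <- record$gamma
  if (use_avg_credibility) {
    if (is.null(record$avg_credibility)) {
      stop_input("use_avg_credibility requires avg_credibility on the record")
    }
    gamma0 <- record$avg_credibility
  }
  post <- beta_posterior(u = record$u, a1 = prior[1], a2 = prior[2])
  ev <- e_value(post, gamma0 = gamma0, method = "analytic")
  dc <- delta_critical_exact(record$n, alpha, gamma = record$gamma,
                             prior = prior)
  dc_rule <- if (length(dc) == 2L) {
    if (record$delta < 0) dc[["lower"]] else dc[["upper"]]
  } else {
    dc
  }
  list(
    e_value = ev,
    delta_critical = dc,
    decisions = list(
      fbst = fbst_decision(ev, alpha),
      delta_rule = if (abs(record$delta) > dc_rule) "reject" else "not_reject"
    )
  )
}

#' @export
print.loo_report <- function(x, ...) {
  r <- x$record
  cat(sprintf("Leave-one-out predictive accuracy (n = %d, gamma = %g, %s intervals)\n",
              r$n, x$gamma, x$kind))
  cat(sprintf("  kappa = %d/%d = %.3f,  Delta = %.3f\n",
              sum(r$u), r$n, r$kappa, r$delta))
  dc <- x$delta_critical
  cat(sprintf("  FBST e-value = %.3f  -> %s (alpha = %g)\n",
              x$e_value$e_value, x$decisions$fbst, x$alpha))
  cat(sprintf("  |Delta| vs critical value %s -> %s\n",
              paste(format(round_half_up(dc, 3)), collapse = "/"),
              x$decisions$delta_rule))
  if (!anyNA(x$rows$y_hat)) {
    cat(sprintf("  RMSE of predictive means = %.3f\n", rmse(x)))
  }
  invisible(x)
}

#' @export
as.data.frame.loo_report <- function(x, ...) x$rows
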