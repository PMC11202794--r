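#include <Rcpp.h>
using namespace Rcpp;

// Log posterior of the exponential regression with rate exp(-x'beta) and
// independent normal priors, up to an additive constant.
static double log_post(const std::vector<double> &beta, const NumericVector &y,
                       const NumericMatrix &X, const NumericVector &pm,
                       const NumericVector &ps) {
  const int n = X.nrow(), p = X.ncol();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * beta[j];
    // exp(-eta) overflows past ~709: treat as an impossible move
    if (eta < -700.0) return R_NegInf;
    ll += -eta - y[i] * std::exp(-eta);
  }
  for (int j = 0; j < p; ++j) {
    double z = (beta[j] - pm[j]) / ps[j];
    ll -= 0.5 * z * z;
  }
  return ll;
}

// Adaptive random-walk Metropolis for the exponential regression.
// propL is the upper Cholesky factor of the proposal covariance; the global
// scale is adapted in batches of 50 during burn-in towards target_acc and
// frozen afterwards. Uses R's RNG, so set.seed() in R makes runs
// bit-reproducible.
// [[Rcpp::export]]
List rwm_expreg_cpp(NumericVector y, NumericMatrix X, NumericVector init,
                    NumericMatrix propL, NumericVector prior_mean,
                    NumericVector prior_sd, int n_iter, int burn_in, int thin,
                    double target_acc) {
  const int p = X.ncol();
  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(n_keep, p);

  std::vector<double> beta(init.begin(), init.end());
  std::vector<double> prop(p), z(p);
  double lp = log_post(beta, y, X, prior_mean, prior_sd);

  double log_scale = 0.0;
  int batch = 0, batch_acc = 0, batch_size = 50;
  int acc_post = 0, kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < p; ++j) z[j] = norm_rand();
    double s = std::exp(log_scale);
    // step = s * t(propL) %*% z  (propL upper triangular)
    for (int j = 0; j < p; ++j) {
      double step = 0.0;
      for (int k = 0; k <= j; ++k) step += propL(k, j) * z[k];
      prop[j] = beta[j] + s * step;
    }
    double lp_prop = log_post(prop, y, X, prior_mean, prior_sd);
    bool accept = R_FINITE(lp_prop) &&
                  (lp_prop - lp > 0.0 || unif_rand() < std::exp(lp_prop - lp));
    if (accept) {
      beta = prop;
      lp = lp_prop;
      if (it <= burn_in) ++batch_acc;
      else ++acc_post;
    }
    if (it <= burn_in && it % batch_size == 0) {
      ++batch;
      double rate = (double)batch_acc / batch_size;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
      log_scale += (rate > target_acc) ? delta : -delta;
      if (log_scale > 5.0) log_scale = 5.0;
      if (log_scale < -5.0) log_scale = -5.0;
      batch_acc = 0;
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < p; ++j) draws(kept, j) = beta[j];
      ++kept;
    }
  }

  double acc_rate = (n_iter > burn_in)
                        ? (double)acc_post / (double)(n_iter - burn_in)
                        : NA_REAL;
  return List::create(_["draws"] = draws, _["acceptance_rate"] = acc_rate,
                      _["log_scale"] = log_scale);
}
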