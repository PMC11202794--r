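---
title: "Assessing Bayesian predictive accuracy with leave-one-out coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing Bayesian predictive accuracy with leave-one-out coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predacc)
```

## The problem

Most Bayesian model-checking tools compare models against each other
(Bayes factors, LPML, WAIC) and so can only say that one candidate is
better than another — never that a model is adequate in absolute terms.
`predacc` implements an absolute check built on a simple idea: a model
that represents the data-generating process well should *predict* well,
and a calibrated way to measure that is to ask how often held-out
observations land inside their predictive credible intervals.

The procedure is leave-one-out (LOO). For each observation $i$ of a
sample of size $n$, the model is refitted without it and a predictive
credible interval $C_i$ of level $\gamma$ is built for it. The coverage
indicator is

$$u_i = \mathbf{1}\{y_i \in C_i\},$$

with $C_i$ closed on both ends (a boundary hit has probability zero for
continuous predictives, and the closed convention matches the discrete
limit definitions below). The proportion of correct predictions and the
accuracy measure are

$$\kappa = \frac{1}{n}\sum_i u_i, \qquad \Delta = \kappa - \gamma .$$

If the model predicts as well as it claims, $\kappa$ should be near
$\gamma$ and $\Delta$ near zero. $\Delta < 0$ flags under-coverage —
the model's predictive intervals miss more often than advertised —
while $\Delta > 0$ flags over-wide, uninformative intervals. Both
directions are failures of calibration.

We use $\gamma = 0.5$ throughout as the default. At that level the
achievable deviations of $\kappa$ below and above $\gamma$ are
symmetric, which makes a single two-sided threshold for $|\Delta|$
meaningful; for $\gamma \neq 0.5$ the package returns separate lower
and upper thresholds.

## The FBST decision rule

Treating the $u_i$ as Bernoulli($\kappa$) with a Beta($a_1, a_2$) prior
gives the posterior $\kappa \mid u \sim \text{Beta}(A_1, A_2)$ with
$A_1 = a_1 + \sum u_i$, $A_2 = a_2 + n - \sum u_i$. The hypothesis
$H: \kappa = \gamma$ is tested with the Full Bayesian Significance Test
(FBST): the evidence value (e-value) is the posterior probability of
the set of $\kappa$ whose density does not exceed the density at
$\gamma$. Small e-values mean $\gamma$ sits far out in the posterior,
discrediting $H$; the rule rejects when e-value $< \alpha$ (strict
inequality, so an e-value exactly equal to $\alpha$ does not reject).

Two routes compute the e-value:

* **Monte Carlo** (`method = "mc"`): draw $M$ values from
  Beta($A_1, A_2$), count the fraction whose density is at most the
  density at $\gamma$ (ties count towards the e-value). The default
  $M = 10^6$ gives a standard error below $5\times 10^{-4}$.
* **Analytic** (`method = "analytic"`, the default): the density level
  set is resolved exactly. For $A_1, A_2 > 1$ the Beta density is
  unimodal, so the level set is two tails whose inner endpoints share
  the density value at $\gamma$; one endpoint is $\gamma$ itself and
  the other is found by bracketed root-finding on the log density
  (tolerance $10^{-12}$), bracketing on the opposite side of the mode.
  The e-value is then two regularized-incomplete-Beta tail masses.
  Monotone ($A_1 \le 1$ or $A_2 \le 1$) and U-shaped densities are
  classified first and handled by direct tail masses. When the
  non-trivial root lies beyond $10^{-15}$ from the support edge the
  corresponding tail mass is below machine precision and the root is
  clamped to the edge.

The two routes agree within Monte Carlo error; the test suite asserts
agreement within $4\sqrt{e(1-e)/M}$ over a grid of configurations.

```{r}
post <- beta_posterior(n = 33, u_sum = 11)   # Beta(12, 23) posterior
e_value(post, gamma0 = 0.5)
```

## Critical values for the accuracy measure

The same decision can be phrased directly on $\Delta$: reject when
$|\Delta_{\text{obs}}|$ exceeds a critical threshold. Because $\kappa$
lives on the grid $\{0, 1/n, \dots, 1\}$, the threshold is calibrated
by computing the analytic e-value at every achievable count
$u \in \{0, \dots, n\}$ and placing the cut midway between the largest
non-rejected and the smallest rejected achievable $|\Delta|$
(`delta_critical_exact()`). The midpoint convention is the one
consistent with the bundled reference table; thresholds are displayed
rounded half-up to 3 decimals.

The calibration uses the analytic e-value rather than Monte Carlo so
the table is deterministic. One consequence worth knowing: at
$n = 24$, $\alpha = 0.01$ the boundary count has e-value $0.010158$ —
within Monte Carlo error of $\alpha$ at $M = 10^6$ — and a Monte Carlo
calibration can flip that single cell by one grid step. The regression
test therefore requires exact agreement with the bundled table in all
but at most one such razor-thin cell.

For $n > 40$ the exact thresholds are well approximated by
$\beta_1/\sqrt{n}$. `fit_beta1()` regenerates the exact thresholds on a
grid of sample sizes (default all integers 10–500, fitted unweighted;
the originating study did not enumerate its grid, so this is the
package's choice) and fits the no-intercept least-squares model
$\xi = \beta_1/\sqrt{n}$ in closed form,
$\hat\beta_1 = \sum_i \xi_i/\sqrt{n_i} \,/\, \sum_i 1/n_i$. Bundled
coefficients for $\alpha = 0.01, 0.05, 0.10, 0.20$ are 1.261, 0.966,
0.812, 0.633.

```{r}
delta_critical_exact(33, alpha = 0.05, rounded = TRUE)
delta_critical_approx(100, alpha = 0.05)
```

## Conjugate predictive models

Two closed-form models serve both as worked examples and as fast
engines for the LOO pipeline.

**Exponential–Gamma.** For $x \mid \theta \sim$ Exponential($\theta$)
(mean $1/\theta$) with $\theta \sim$ Gamma($a, b$), the posterior is
Gamma($a+n, b+\sum x_i$) and the predictive is Lomax:
$f(y) = (a+n)(b+S)^{a+n}/(y+b+S)^{a+n+1}$ with quantile
$y_q = (b+S)\,[(1-q)^{-1/(a+n)} - 1]$. The equal-tailed $\gamma$
interval takes the $(1-\gamma)/2$ and $(1+\gamma)/2$ quantiles.
Leave-one-out refits are sufficient-statistic subtractions,
$(n-1,\, S - x_i)$, so no refitting loop is needed.

**Poisson–Gamma.** For counts, the predictive is Gamma–Poisson
(negative binomial) with $A = a + \sum x_i$, $B = b + n$. The pmf is
evaluated in log space and the cdf by the recurrence
$f(y{+}1)/f(y) = (A+y)/((y{+}1)(B{+}1))$, truncated once the
accumulated mass reaches $1 - 10^{-12}$. The discrete equal-tailed
limits are $L_1 = \sup\{y : F(y) \le (1-\gamma)/2\}$ and
$L_2 = \inf\{y : F(y) \ge (1+\gamma)/2\}$, splitting the excluded mass
evenly; when the $L_1$ condition holds for no $y$, $L_1 = 0$ so the
interval stays inside the support. Because the support is discrete the
*realized* credibility $F(L_2) - F(L_1 - 1)$ is at least $\gamma$, and
the decision rule can optionally test $\kappa$ against the average
realized credibility $\kappa^*$ of the $n$ LOO intervals instead of
$\gamma$ (`use_avg_credibility`).

The diffuse prior used in examples is Gamma($10^{-2}, 10^{-2}$).

HPD intervals are computed empirically from predictive draws as the
shortest window of $\lceil \gamma J \rceil$ consecutive order
statistics, returning the left-most window on ties for deterministic
output. Equal-tailed intervals are the default everywhere — the
critical-value calibration was built with them — and HPD is offered
for the continuous models only.

## Exponential regression by MCMC

For covariate-dependent data the package fits
$y_i \sim \text{Exponential}(\theta_i)$ with
$\theta_i = \exp(-x_i^\top\beta)$, i.e. mean response
$\exp(x_i^\top\beta)$, under independent normal priors (default the
diffuse $N(0, 100^2)$). The sampler is adaptive random-walk Metropolis
on the full coefficient vector:

* initialisation at the MAP, found by BFGS with the analytic gradient —
  this removes burn-in sensitivity at test-scale chain lengths;
* multivariate normal proposal with covariance equal to the inverse
  curvature at the MAP scaled by $2.38^2/p$;
* a global proposal scale adapted in batches of 50 during burn-in
  towards 30% acceptance, frozen afterwards (so the post-burn-in chain
  is a valid Metropolis chain);
* the core loop is compiled code driven by R's RNG, so `set.seed()`
  makes chains bit-reproducible.

Predictive draws for a new row take one Exponential draw per retained
posterior draw; the predictive mean is the sample mean and equal-tailed
intervals come from sample quantiles. The package default chain
(1,000,000 iterations, burn-in 10,000, thinning 5) matches the
reference analysis of the bundled leukemia data; tests and the
acceptance script run reduced chains (50,000/5,000/5), which reproduce
the leukemia coverage count and RMSE comfortably.

A note on the bundled leukemia example: with columns
(intercept, `wbc`, `ag`) the full-data posterior means are
approximately $(3.16, -0.064, 1.11)$ — white-cell count shortens
survival, the AG-positive marker lengthens it. Coefficients are always
ordered as the model formula states, here `time ~ wbc + ag`.

## The leave-one-out engine

`run_loo()` accepts any model factory implementing `fit_model()` and
`predict_interval()`; conjugate and MCMC models share the engine. For
MCMC models each LOO fit gets a fresh seed derived deterministically
from the master seed, keeping runs reproducible without correlating
chains across fits. The report carries the per-observation intervals,
$\kappa$, $\Delta$, the FBST e-value, the exact critical value, and
both decisions. If a subset fit fails (for example a covariate becomes
constant after removing a row) the error names the offending row; no
imputation is attempted.

```{r}
d <- leukemia_data()
model <- exp_reg_model(time ~ wbc + ag, n_iter = 50000, burn_in = 5000,
                       thin = 5)
report <- run_loo(model, d, gamma = 0.5, alpha = 0.05, seed = 42)
report
```

## The simulation study

`run_study()` examines how the sampling distribution of $\kappa$
depends on design factors. Datasets are simulated from exponential
regressions under four fixed coefficient scenarios with up to five
covariates drawn as $X_1 \sim U(0,5)$, $X_2 \sim$ Bernoulli(0.2),
$X_3 \sim N(0,1)$, $X_4 \sim$ Bernoulli(0.7), $X_5 \sim U(0,5)$;
models with $k < 5$ covariates use the first $k$ terms (the originating
design does not specify the subset; the nested prefix is chosen for
determinism). Each cell reports the mean, standard deviation and
skewness (standardised third central moment) of $\kappa$.

The qualitative findings the tests assert: with small $n$ and many
covariates the model saturates and over-covers (higher mean and SD of
$\kappa$); as $n$ grows all cells converge to mean $\gamma$ with SD
shrinking towards zero; the coefficient scenarios themselves do not
shift $\kappa$; and the $\kappa$ distributions stay near-symmetric.
This is what justifies calibrating the critical values on $n$ alone.

The full-scale design (1000 replicates per cell, long chains) takes
hours; the package defaults are reduced (100 replicates, 20,000-draw
chains) and the test suite reduces further (tens of replicates,
3,000-draw chains), which is enough to reproduce the orderings above
but not to estimate tail quantiles of $\kappa$'s distribution.

## What the synthetic data do and do not show

The generator draws i.i.d. rows from fully specified exponential
regressions — the well-specified case. Passing calibration tests on it
shows the pipeline is internally consistent (type-I error near
$\alpha$, coverage near $\gamma$); it does not certify behaviour under
censoring, heteroscedastic noise, correlated covariates or model
misspecification beyond the specific Poisson-vs-negative-binomial and
misspecified-prior examples exercised in the tests.

## Numerical choices and limitations

* Root-finding tolerance $10^{-12}$; quantile/cdf inversion verified to
  $10^{-10}$; discrete cdf truncation at $1 - 10^{-12}$.
* $\kappa$ and $\Delta$ are kept at full precision; 3-decimal half-up
  rounding is display-only.
* The type-I error of the $\Delta$-rule is exactly the FBST's on the
  achievable grid, which can sit below $\alpha$ for small $n$ (grid
  discreteness); LOO indicators are also weakly dependent, so observed
  rejection rates run slightly conservative.
* The FBST here tests a point null on a Beta-distributed proportion
  only; no loss-function elicitation of $\alpha$ is provided.
* Survival-type censoring is not modelled; the leukemia times are
  treated as fully observed deaths, as in the reference analysis.
* `run_loo()` refits $n$ models; for large $n$ with MCMC this is the
  dominant cost. Conjugate models avoid it entirely via
  sufficient-statistic subtraction.
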