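---
title: "Score-based CUSUM monitoring of INGARCH count series: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based CUSUM monitoring of INGARCH count series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ingarchmonitor)
```

## The model and the monitoring problem

The package watches a stream of counts $Y_1, Y_2, \dots$ for a change in
the parameter of an integer-valued GARCH(1,1) model. The conditional law
of $Y_t$ given its past is a one-parameter exponential family
$p(y \mid \eta) = \exp\{\eta y - A(\eta)\}h(y)$ whose mean
$X_t = B(\eta_t)$, $B = A'$, follows the linear recursion
$$X_t = \omega + a X_{t-1} + b Y_{t-1}, \qquad
  \theta = (\omega, a, b),\ \omega > 0,\ a + b < 1.$$
The contraction $a + b < 1$ gives strict stationarity and ergodicity and
makes the filtered mean forget its initialization geometrically. Two
families are instantiated: Poisson ($B(\eta) = e^\eta$, conditional
variance equal to the mean) and negative binomial with fixed integer
size $r$ ($\eta = \log(1-p)$, mean $r e^\eta/(1 - e^\eta)$,
overdispersed). The size $r$ is treated as known and is not estimated.

Monitoring is *closed-end*: a training sample of length $m$ precedes a
monitoring stream whose planned horizon $n$ is fixed in advance, and all
statistics are scaled by $n^{-1/2}$ with the planned horizon even at
interim steps. The control limit is calibrated so that the probability
of *any* false alarm within the horizon is the nominal level (Type I
error, not average run length).

## Robust estimation

Parameters are estimated by minimum density power divergence. The
per-observation loss at tuning parameter $\alpha \ge 0$ is
$$\tilde l_{\alpha,t}(\theta) =
  \sum_{y \ge 0} p^{1+\alpha}(y \mid \tilde\eta_t(\theta))
  - \Bigl(1 + \tfrac1\alpha\Bigr) p^{\alpha}(Y_t \mid \tilde\eta_t(\theta)),$$
reducing to the negative conditional log-likelihood as $\alpha \to 0$,
so $\alpha = 0$ *is* the MLE. The factor $p^\alpha(Y_t\mid\cdot)$
downweights observations that are improbable under the current filtered
mean, which is what buys robustness to outliers at a small efficiency
cost; on clean data the asymptotic variance is nondecreasing in
$\alpha$ (verified in the test suite by long-run evaluation of
$J_\alpha^{-1} K_\alpha J_\alpha^{-1}$). In practice $\alpha \in (0, 0.3]$
is the useful range; the package takes $\alpha$ as a user choice and
does not implement data-driven selection.

Numerical choices:

* The infinite support sums are truncated at the smallest count whose
  cumulative probability reaches $1 - 10^{-12}$ (a tail mass below the
  float precision of the losses), with a hard ceiling of 10\,000 counts;
  all pmf work is done in log space because $p^{1+\alpha}$ underflows
  quickly for moderate counts.
* The filtered mean and its gradient are exact linear recursions and run
  through `stats::filter(method = "recursive")`; the gradient recursion
  starts at zero because the initial value $\tilde X_1$ is a constant.
* $\tilde X_1$ defaults to the training-sample mean (the model leaves it
  free; geometric forgetting makes the choice asymptotically
  immaterial).
* Optimization is over a smooth reparameterization that enforces the
  compact space: $\omega = e^{u_1}$ (with a box guard
  $[10^{-3}, 10\bar Y]$), $a + b = \epsilon + (1 - 2\epsilon)
  \mathrm{logit}^{-1}(u_2)$ with $\epsilon = 10^{-3}$, and the split
  $a : b$ through a third logistic coordinate. The optimizer is `nlminb`
  with the analytic score-based gradient; convergence is declared on the
  optimizer's own criterion or a numerically zero gradient, and up to
  three jittered restarts are attempted otherwise. The default start is
  a moment start, $a = b = 0.2$, $\omega = (1 - 0.4)\bar Y$.
* The sandwich covariance $\hat J^{-1}\hat K\hat J^{-1}/n$ uses the
  outer-product estimate $\hat K$ and a numerical Hessian $\hat J$
  (`stats::optimHess`); $\hat J$ is reported as the positive-definite
  Hessian of the minimized objective, the sign convention under which
  the information identity $\hat K \approx \hat J$ holds at the MLE.

## The three charts and their limits

With score vectors $s_t = \partial \tilde l_{\alpha,t}/\partial\theta$
evaluated either at a known $\theta_0$ or at the training-sample MDPDE
$\hat\theta_{\alpha,m}$, and
$\hat K_\alpha = m^{-1}\sum_{t \le m} s_t s_t^{\top}$ from the *training*
scores at the same parameter, the normalized partial-sum process is
$W_k = \hat K_\alpha^{-1/2} \sum_{t \le k} s_t$. The charts are

* **min**: $\max_k n^{-1/2}\,\|\min_{j\le k} W_j - W_k\|_{\max}$,
* **max**: $\max_k n^{-1/2}\,\|\max_{j\le k} W_j - W_k\|_{\max}$
  (componentwise running extrema, max-norm),
* **cusum**: $\max_{i<j\le k} n^{-1/2}\,\|(i/j) W_j - W_i\|$
  (Euclidean norm).

Under no change the min and max charts share the limit
$T = \sup_{0\le s\le 1}\|B_3(s)\|_{\max}$, whose level-$\alpha_0$
quantile follows from the per-component rule
$P(\sup|B| \ge c) = 1 - (1-\alpha_0)^{1/3}$ and the alternating
reflection series for the scalar boundary-crossing probability (summed
to $10^{-14}$, inverted by bracketed root finding; 2.633 at the 0.05
level). The cusum chart converges to a weighted Brownian-bridge
functional with no closed form; because the bridge terms cancel in
$(s/s')B^\circ(s') - B^\circ(s)$, the Monte Carlo limit simulates plain
Brownian motion on a grid (defaults 2000 steps, 20000 replications;
the discretization bias of sup functionals shrinks like the square root
of the step size and is not corrected). Computed quantiles can be
cached to JSON keyed by their settings.

Norm conventions follow the statistics' definitions: max-norm for the
min/max charts, Euclidean norm for the cusum chart and its limit. The
eigenvalue floor in $\hat K^{-1/2}$ (relative $10^{-10}$) guards
near-singular score covariances from short training samples; training
samples under 50 observations trigger a warning.

In estimated-parameter mode the limit theory needs $m$ large relative
to $n$ for the min/max charts, yet studies routinely use $m = n$; a
parametric bootstrap from the fitted model reduces this
parameter-estimation effect, so bootstrap limits are the recommended
source in estimated mode and both are provided. The warp-speed variant
used by the study runner draws a single bootstrap replicate per Monte
Carlo replication and pools the replicates into one critical value per
cell, cutting the cost of limit estimation by the bootstrap size.

## The simulation harness

`change_scenario()`/`simulate_scenario()` encode the study design: a
Poisson INGARCH(1,1) baseline, one of four change patterns (all of
$(\omega,a,b)$, or each coordinate alone, scaled by $1+\delta$) applied
at a change time $\tau$ (defaults to mid-stream) with the conditional
mean carried continuously across the change, and optional contamination
$(1-p_t)Y_t + p_t Z_t$ with Bernoulli($p$) switches to iid
Poisson($\lambda$) outliers. Contamination is applied after generation —
outliers do not feed back into the recursion — and, when present, to
both the training sample and the stream, since both are draws from the
same observed law; bootstrap samples, by contrast, are generated from
the fitted clean model. Simulated paths start at the stationary mean
and discard a 500-observation burn-in, negligible initialization bias
at $a + b \le 0.8$.

What the generator does *not* emulate: real surveillance series have
covariates, seasonality, reporting delays and slowly drifting baselines;
passing size/power checks on the generator shows correctness of the
procedure under the stated model, not performance on such data.

Replication seeds are derived from one master seed by a counter scheme
(cell and replication indices), so any cell of a study is independently
reproducible.

## Problem sizes and reproduction scale

The bundled reproduction uses 1000 replications for the known-parameter
cells ($m = n = 500$ or $1000$) and 200 replications for the
warp-bootstrap contaminated cells ($m = n = 1000$), sizes at which the
binomial error of a rejection rate is quantified and reported alongside
each cell ($\pm 3$ standard errors is the acceptance band used in the
tests). The study runner takes the full grid and any replication count
by argument.

## Known limitations

* Only INGARCH(1,1) with the linear mean recursion is instantiated;
  higher orders and nonlinear recursions are out of scope.
* The negative binomial size $r$ is fixed, not estimated.
* Open-end (infinite-horizon) monitoring and ARL-based calibration are
  not provided.
* Under heavy contamination the MLE-based ($\alpha = 0$) chart is the
  wrong tool — that is the point of the package — but the MDPDE chart's
  robustness also degrades as $\lambda$ approaches the post-change
  level, where outliers and genuine change become indistinguishable.
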