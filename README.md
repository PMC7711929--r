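# ingarchmonitor

Robust online monitoring of parameter change in count time series.

Many surveillance problems — disease case counts, adverse-event reports,
numbers of extreme price movements — produce a stream of non-negative
integers whose level and dependence must be watched for structural change.
`ingarchmonitor` implements score-based CUSUM control charts for the
integer-valued GARCH(1,1) model with a one-parameter exponential-family
conditional law,

    Y_t | F_{t-1} ~ p(y | eta_t),   X_t := E(Y_t | F_{t-1}) = omega + a X_{t-1} + b Y_{t-1},

with `p(y|eta) = exp{eta y - A(eta)} h(y)` (Poisson or negative binomial
with fixed size r), parameter `theta = (omega, a, b)`, `omega > 0` and
`a + b < 1`.

Estimation uses the minimum density power divergence estimator (MDPDE)
with per-observation loss

    l_{alpha,t}(theta) = sum_y p^{1+alpha}(y|eta_t) - (1 + 1/alpha) p^alpha(Y_t|eta_t)   (alpha > 0)
                       = -log p(Y_t|eta_t)                                               (alpha = 0),

so `alpha = 0` is the conditional MLE and larger `alpha` trades a little
efficiency for robustness to outliers. Given a training sample of length
m and a monitoring stream of length n, the charts cumulate the score
vectors `s_t = d l_{alpha,t}/d theta` (at the true parameter or at the
training-sample MDPDE), normalized by the inverse square root of the
empirical score covariance `K_hat = m^{-1} sum s_t s_t'`:

    W_k = K_hat^{-1/2} sum_{t<=k} s_t,

and monitor three closed-end statistics over the planned horizon n —
a min-type and a max-type chart (max-norm distance of `W_k` from its
running componentwise extrema, scaled by `n^{-1/2}`) and a pairwise
cusum-type chart `max_{i<j<=k} n^{-1/2} ||(i/j) W_j - W_i||`. Under no
change these converge to `sup ||B_3(s)||_max` (min/max) and a weighted
Brownian-bridge functional (cusum); control limits come from the
reflection-series quantile (e.g. 2.633 at level 0.05 for d = 3), from
Monte Carlo simulation of the limit functional, or from a parametric
(optionally warp-speed) bootstrap. An alarm is raised at the first k
whose statistic exceeds the limit.

The package also ships the full simulation harness: a scenario generator
with four change patterns (all parameters, omega-only, a-only, b-only
scaled by `1 + delta` at a change time tau), Bernoulli–Poisson outlier
contamination `(1-p_t) Y_t + p_t Z_t`, and a size/power study runner.

## Worked example

```r
library(ingarchmonitor)
set.seed(42)
fam   <- count_family("poisson")
theta0 <- ingarch_params(2, 0.3, 0.3)          # stationary mean 5
train  <- simulate_ingarch(theta0, 500, fam)
stream <- simulate_change(theta0, c(2, 0.45, 0.3), tau = 250, n = 500, fam = fam)

fit <- mdpde(train, alpha = 0.1, fam = fam)
fit
#> MDPDE fit (alpha = 0.1, family = poisson, n = 500)
#>           omega      a      b
#> estimate 2.1089 0.2056 0.3585
#> se       0.4570 0.1126 0.0455
#> objective = -8.046270, converged = TRUE

mon <- monitor_change(stream, train, fam, alpha = 0.1, mode = "estimated",
                      statistic = c("min", "cusum"), limit = "bootstrap",
                      boot_B = 200, seed = 1)
mon
#> INGARCH monitoring (estimated parameter, alpha = 0.1, m = 500, n = 500)
#> theta used: omega = 2.1089, a = 0.2056, b = 0.3585
#>   min   chart: statistic 12.1737 vs limit 2.9582 (bootstrap) -> alarm at k = 288
#>   cusum chart: statistic 8.0710 vs limit 1.9833 (bootstrap) -> alarm at k = 286
```

The fitted parameters recover the training regime; both charts cross
their bootstrap control limits shortly after the change at k = 250 (the
a-coefficient rises from 0.30 to 0.45, lifting the long-run mean from 5
to 8), so an alarm is raised and its first-crossing time reported.

Empirical size/power tables are produced by `run_size_power()`, e.g.

```r
sc <- change_scenario(theta0, case = 3, delta = 0.5, n = 500, m = 500)
run_size_power(sc, alphas = c(0, 0.1), statistics = "min", mode = "known", R = 500)
```

A command-line wrapper with `simulate`, `limits`, `monitor` and
`size-power` subcommands is installed under `inst/cli/ingarchmonitor.R`.

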