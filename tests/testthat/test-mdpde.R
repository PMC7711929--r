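test_that("DPD loss reduces to the negative log-likelihood at alpha 0 and
           matches a brute-force truncated sum at alpha > 0", {
  fam <- count_family("poisson")
  expect_equal(dpd_loss(2, log(2), alpha = 0, fam),
               -log(2 * exp(-2)), tolerance = 1e-12)
  expect_equal(dpd_loss(0:6, log(3), alpha = 0, fam),
               -dpois(0:6, 3, log = TRUE), tolerance = 1e-12)

  # independent oracle: direct pmf powers summed over the support
  for (al in c(0.1, 0.5)) for (mu in c(1, 4.5)) for (yobs in c(0L, 3L)) {
    ys <- 0:200
    oracle <- sum(dpois(ys, mu)^(1 + al)) -
      (1 + 1 / al) * dpois(yobs, mu)^al
    expect_equal(dpd_loss(yobs, log(mu), alpha = al, fam), oracle,
                 tolerance = 1e-10)
  }
})

test_that("analytic scores equal finite differences of the objective", {
  fam <- count_family("poisson")
  set.seed(11)
  y <- simulate_ingarch(ingarch_params(2, 0.3, 0.3), 150)
  thetas <- list(c(2, 0.3, 0.3), c(1.2, 0.1, 0.5), c(3.5, 0.45, 0.05))
  for (al in c(0, 0.1, 0.3)) for (th in thetas) {
    fs <- ingarch_filter(y, th, x1 = mean(y), fam = fam)
    g_an <- colMeans(score_path(y, fs, al, fam)$scores)
    g_fd <- fd_objective_grad(y, th, al, fam, x1 = mean(y))
    expect_equal(g_an, g_fd, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("scores are continuous in alpha at zero and vanish at the mean", {
  fam <- count_family("poisson")
  set.seed(12)
  y <- simulate_ingarch(ingarch_params(2, 0.2, 0.4), 100)
  fs <- ingarch_filter(y, c(2, 0.2, 0.4), x1 = mean(y), fam = fam)
  s0 <- score_path(y, fs, 0, fam)$scores
  s1 <- score_path(y, fs, 1e-6, fam)$scores
  expect_equal(s0, s1, tolerance = 1e-3)

  # alpha = 0 score is zero when the observation equals the filtered mean
  fs2 <- ingarch_filter(c(2L, 2L, 2L), c(2, 0, 0), x1 = 2, fam = fam)
  expect_equal(score_path(c(2L, 2L, 2L), fs2, 0, fam)$scores,
               matrix(0, 3, 3), ignore_attr = TRUE)
})

test_that("objective averages the per-observation losses", {
  fam <- count_family("poisson")
  y <- c(3L, 1L)
  fs <- ingarch_filter(y, c(1, 0.5, 0.5), x1 = 2, fam = fam)
  by_hand <- mean(c(-dpois(3, 2, log = TRUE), -dpois(1, 3.5, log = TRUE)))
  expect_equal(mdpde_objective(y, c(1, 0.5, 0.5), 0, fam, x1 = 2), by_hand,
               tolerance = 1e-12)
})

test_that("score covariance is an outer-product average and PSD", {
  v <- c(1, -2, 0.5)
  S <- matrix(v, nrow = 5, ncol = 3, byrow = TRUE)
  expect_equal(score_cov(S), tcrossprod(v), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:5) {
    S <- matrix(rnorm(60), 20, 3)
    expect_gte(min(eigen(score_cov(S), symmetric = TRUE)$values), -1e-10)
  }
  expect_error(score_cov(matrix(1, 2, 3)), "at least 3")
})

test_that("outer-product and Hessian information estimates agree at the MLE
           on a long null path", {
  fam <- count_family("poisson")
  set.seed(14)
  y <- simulate_ingarch(ingarch_params(2, 0.3, 0.3), 3000)
  fit <- mdpde(y, alpha = 0, fam = fam)
  expect_true(fit$converged)
  rel <- norm(fit$khat - fit$jhat, "F") / norm(fit$jhat, "F")
  expect_lt(rel, 0.1)
  # minimizer beats the truth on the evaluated objective
  expect_lte(fit$objective_value,
             mdpde_objective(y, c(2, 0.3, 0.3), 0, fam, x1 = mean(y)))
})

test_that("mean score at the truth is centered on a long null path", {
  fam <- count_family("poisson")
  set.seed(15)
  y <- simulate_ingarch(ingarch_params(2, 0.3, 0.3), 4000)
  fs <- ingarch_filter(y, c(2, 0.3, 0.3), x1 = mean(y), fam = fam)
  for (al in c(0, 0.2)) {
    S <- score_path(y, fs, al, fam)$scores
    se <- sqrt(diag(score_cov(S)) / nrow(S))
    expect_true(all(abs(colMeans(S)) < 3 * se))
  }
})

test_that("asymptotic variance is nondecreasing in alpha on clean data", {
  # efficiency ordering J^-1 K J^-1: computed at the true parameter from
  # long-run sample averages, avoiding Monte Carlo fit noise
  fam <- count_family("poisson")
  set.seed(16)
  th0 <- c(2, 0.3, 0.3)
  y <- simulate_ingarch(ingarch_params(2, 0.3, 0.3), 10000)
  avar <- vapply(c(0, 0.1, 0.2, 0.3), function(al) {
    fs <- ingarch_filter(y, th0, x1 = mean(y), fam = fam)
    K <- score_cov(score_path(y, fs, al, fam)$scores)
    J <- stats::optimHess(th0, function(t)
      mdpde_objective(y, t, al, fam, x1 = mean(y)))
    sum(diag(solve(J, K) %*% solve(J)))
  }, numeric(1))
  expect_true(all(diff(avar) > 0))
})

test_that("robust fits resist Poisson outlier contamination in omega", {
  fam <- count_family("poisson")
  set.seed(17)
  om <- replicate(40, {
    y <- contaminate(simulate_ingarch(ingarch_params(2, 0.2, 0.2), 400),
                     p = 0.1, lam = 30)
    c(mdpde(y, 0, fam)$theta_hat[1], mdpde(y, 0.3, fam)$theta_hat[1])
  })
  bias_mle <- abs(mean(om[1, ]) - 2)
  bias_dpd <- abs(mean(om[2, ]) - 2)
  expect_lt(bias_dpd, bias_mle)
})

test_that("fit serializes to JSON with its key fields", {
  fam <- count_family("poisson")
  set.seed(18)
  y <- simulate_ingarch(ingarch_params(2, 0.2, 0.3), 300)
  fit <- mdpde(y, alpha = 0.1, fam = fam)
  js <- jsonlite::fromJSON(fit_json(fit))
  expect_equal(js$alpha, 0.1)
  expect_equal(js$n_obs, 300L)
  expect_equal(unlist(js$theta_hat), unclass(fit$theta_hat),
               tolerance = 1e-10, ignore_attr = TRUE)
})
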