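test_that("inverse square root inverts PSD matrices", {
  expect_equal(psd_inv_sqrt(diag(3)), diag(3), tolerance = 1e-12)
  expect_equal(psd_inv_sqrt(diag(c(4, 9, 16))), diag(c(1/2, 1/3, 1/4)),
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:10) {
    M <- random_psd()
    R <- psd_inv_sqrt(M)
    expect_lt(norm(R %*% M %*% R - diag(3), "F"), 1e-8)
    expect_lt(max(abs(R - t(R))), 1e-10)
  }
  expect_error(psd_inv_sqrt(matrix(0, 3, 3)), "zero")
  expect_error(psd_inv_sqrt(matrix(1:9, 3)), "symmetric")
})

test_that("the W process cumulates normalized scores", {
  S <- matrix(0, 5, 3)
  expect_equal(w_process(S, diag(3))$w, S)
  s <- c(1, 2, -1)
  expect_equal(w_process(rbind(s), diag(3))$w, rbind(s), ignore_attr = TRUE)
  set.seed(22)
  S <- matrix(rnorm(30), 10, 3)
  K <- random_psd()
  W <- w_process(S, K)$w
  expect_equal(W[10, ], drop(psd_inv_sqrt(K) %*% colSums(S)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("statistics match the exhaustive enumeration oracle for short paths", {
  set.seed(23)
  for (i in 1:8) {
    k <- sample(2:8, 1)
    W <- matrix(rnorm(k * 3), k, 3)
    got <- stat_paths(W, n = k)
    want <- oracle_stat_paths(W, n = k)
    expect_equal(got$min, want$min, tolerance = 1e-12)
    expect_equal(got$max, want$max, tolerance = 1e-12)
    expect_equal(got$cusum, want$cusum, tolerance = 1e-12)
  }
})

test_that("statistic paths have the structural properties", {
  W <- matrix(2, 6, 3)  # constant path: running-extremum differences vanish
  p <- stat_paths(W, 6)
  expect_equal(p$min, rep(0, 6)); expect_equal(p$max, rep(0, 6))
  p0 <- stat_paths(matrix(0, 6, 3), 6)  # zero path: every chart vanishes
  expect_equal(p0$cusum, rep(0, 6))
  set.seed(24)
  W <- apply(matrix(rnorm(60), 20, 3), 2, cumsum)
  p <- stat_paths(W, 20)
  expect_true(all(diff(p$cusum) >= 0))
  expect_true(all(p$min >= 0) && all(p$max >= 0))
  expect_error(stat_paths(W, 10), "horizon")
})

test_that("min and max charts share their limiting distribution under H0", {
  # random-walk approximation of the Brownian functional, 2000 paths
  set.seed(25)
  n <- 1000
  q <- replicate(2000, {
    W <- apply(matrix(rnorm(n * 3, sd = 1), n, 3), 2, cumsum)
    lo <- apply(W, 2, cummin); hi <- apply(W, 2, cummax)
    c(max(abs(lo - W)), max(abs(hi - W))) / sqrt(n)
  })
  q95 <- apply(q, 1, quantile, 0.95)
  expect_lt(abs(q95[1] - q95[2]), 0.1)
})

test_that("the pairwise cusum functional is identical on bridge and motion", {
  set.seed(26)
  n <- 200
  B <- apply(matrix(rnorm(n * 3, sd = sqrt(1 / n)), n, 3), 2, cumsum)
  Bo <- B - (seq_len(n) / n) %o% B[n, ]   # Brownian bridge
  expect_equal(stat_paths(B, n)$cusum, stat_paths(Bo, n)$cusum,
               tolerance = 1e-10)
})

test_that("monitoring raises alarms after a large change but not before", {
  fam <- count_family("poisson")
  set.seed(27)
  th0 <- ingarch_params(2, 0.2, 0.3)
  train <- simulate_ingarch(th0, 400, fam)
  stream <- simulate_change(th0, c(4, 0.4, 0.45), tau = 150, n = 300, fam = fam)
  mon <- monitor_change(stream, train, fam, alpha = 0, mode = "known",
                        theta0 = th0, statistic = c("min", "cusum"),
                        limit = "mc", mc_grid = 500, mc_reps = 2000, seed = 1)
  for (ch in mon$charts) {
    expect_false(is.na(ch$alarm_time))
    expect_equal(ch$overall, max(ch$path))
  }
  # the same stream with no change rarely alarms; check one H0 draw
  stream0 <- simulate_ingarch(th0, 300, fam)
  mon0 <- monitor_change(stream0, train, fam, alpha = 0, mode = "known",
                         theta0 = th0, statistic = "min", limit = "analytic")
  expect_lt(mon0$charts$min$overall, 4)
  expect_output(print(mon0), "chart")
})

test_that("bootstrap limits are positive and monotone in the level", {
  fam <- count_family("poisson")
  set.seed(28)
  y <- simulate_ingarch(ingarch_params(2, 0.2, 0.2), 150, fam)
  fit <- mdpde(y, 0, fam)
  l05 <- bootstrap_limit(fit, m = 100, n = 100, statistic = "cusum",
                         level = 0.05, B = 100, fam = fam, seed = 9)
  l20 <- bootstrap_limit(fit, m = 100, n = 100, statistic = "cusum",
                         level = 0.20, B = 100, fam = fam, seed = 9)
  expect_gt(l05, 0)
  expect_gte(l05, l20)
})
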