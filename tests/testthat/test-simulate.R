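test_that("simulated paths have the stationary mean and overdispersion", {
  fam <- count_family("poisson")
  set.seed(41)
  y <- simulate_ingarch(ingarch_params(2, 0.3, 0.3), 3e4, fam)
  # stationary variance exceeds the mean for a + b > 0 (Poisson INGARCH)
  expect_lt(abs(mean(y) - 5), 3 * sd(y) / sqrt(length(y) / 10))
  expect_gt(var(y), mean(y))

  y0 <- simulate_ingarch(ingarch_params(3, 0, 0), 2e4, fam)
  expect_lt(abs(mean(y0) - 3), 3 * sqrt(3 / 2e4))
  expect_lt(abs(var(y0) / mean(y0) - 1), 0.05)   # iid Poisson at a = b = 0
})

test_that("a no-change stream is draw-for-draw a plain path", {
  th <- ingarch_params(2, 0.25, 0.35)
  set.seed(42); a <- simulate_ingarch(th, 300)
  set.seed(42); b <- simulate_change(th, th, tau = 150, n = 300)
  expect_identical(a, b)
  set.seed(42); c2 <- simulate_change(th, th, tau = NULL, n = 300)
  expect_identical(a, c2)
})

test_that("a parameter change shifts the post-change level", {
  set.seed(43)
  sc <- change_scenario(ingarch_params(2, 0.3, 0.3), case = 3, delta = 0.5,
                        tau = 500, n = 2000, m = 100)
  expect_equal(sc$theta1, c(omega = 2, a = 0.45, b = 0.3))
  # post-change long-run mean 2 / (1 - 0.45 - 0.3) = 8 vs 5 before
  d <- simulate_scenario(sc, seed = 5)
  pre <- mean(d$stream[1:499]); post <- mean(d$stream[1200:2000])
  expect_gt(post, pre + 1)
  expect_lt(abs(post - 8), 1.5)
  # fixed seed reproduces both segments
  d2 <- simulate_scenario(sc, seed = 5)
  expect_identical(d, d2)
})

test_that("scenario constructor enforces the parameter space", {
  expect_error(change_scenario(ingarch_params(2, 0.6, 0.3), case = 1,
                               delta = 0.25, n = 100), "contraction")
  expect_error(change_scenario(ingarch_params(2, 0.1, 0.1), case = 1,
                               delta = 0, tau = 200, n = 100), "tau")
})

test_that("contamination replaces the right fraction without feedback", {
  set.seed(44)
  y <- simulate_ingarch(ingarch_params(2, 0.2, 0.2), 2e4)
  expect_identical(contaminate(y, 0), y)
  z <- contaminate(y, 0.1, 30)
  frac <- mean(z != y)
  # replaced fraction ~ p (slightly less when Z coincides with Y)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 2e4) + 0.01)
  mix_mean <- 0.9 * mean(y) + 0.1 * 30
  expect_lt(abs(mean(z) - mix_mean), 3 * sd(z) / sqrt(2e4) + 0.05)
  expect_error(contaminate(y, 0.2), "lam")
})

test_that("count series round-trip through one-column files", {
  y <- c(0L, 3L, 12L, 1L)
  f <- tempfile(fileext = ".csv")
  write_counts(y, f)
  expect_identical(read_counts(f), y)
  f2 <- tempfile()
  writeLines(c("5", "2", "0"), f2)        # headerless
  expect_identical(read_counts(f2), c(5L, 2L, 0L))
})
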