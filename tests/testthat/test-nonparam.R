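test_that("runs test reproduces exact combinatorial tail probabilities", {
  # perfectly alternating 10 points: the maximum possible run count
  r <- runs_test(rep(c(1, -1), 5))
  expect_identical(r$n_runs, 10L)
  expect_identical(r$method, "exact")
  expect_equal(r$p_upper, 2 / 252)
  # 5 runs among 11 above / 11 below
  y <- c(rep(5, 11), rep(-5, 11))
  y <- y[c(1:5, 12:16, 6:8, 17:19, 9:11, 20:22)]  # 6 runs
  r2 <- runs_test(y)
  expect_identical(r2$n_above, 11L)
  expect_identical(r2$n_runs, 6L)
  # frozen from the combinatorial formula summed for r = 2..5
  pmf <- wardwalk:::runs_exact_pmf(11, 11)
  expect_equal(sum(pmf[1:4]), 1122 / 705432)
  expect_equal(sum(pmf), 1)
  expect_error(runs_test(rep(3, 10)), "degenerate")
})

test_that("exact runs probabilities equal the enumeration oracle", {
  for (s in 1:8) {
    y <- gen_gaussian(sample(c(8, 10, 12), 1), seed = 300 + s)
    r <- runs_test(y)
    o <- runs_enum_oracle(r$n_above, r$n_below, r$n_runs)
    expect_equal(r$p_lower, unname(o["p_lower"]), tolerance = 1e-12)
    expect_equal(r$p_upper, unname(o["p_upper"]), tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact runs distribution", {
  for (s in 1:25) {
    y <- gen_gaussian(2 * sample(10:20, 1), seed = 800 + s)
    exact <- runs_test(y, exact_max = 40)
    approx <- runs_test(y, exact_max = 0)
    expect_lt(abs(exact$p_lower - approx$p_lower), 0.02)
  }
})

test_that("white noise produces about n/2 + 1 runs", {
  n <- 60
  runs <- vapply(1:500, function(s)
    runs_test(gen_gaussian(n, seed = 2000 + s))$n_runs, integer(1))
  expect_lt(abs(mean(runs) - (n / 2 + 1)) / (n / 2 + 1), 0.05)
})

test_that("Hodges-Lehmann estimate is the median of Walsh averages", {
  h <- hl_median_ci(c(1, 2, 3))
  expect_equal(h$estimate, 2)     # Walsh set {1, 1.5, 2, 2, 2.5, 3}
  h1 <- hl_median_ci(7)
  expect_equal(h1$estimate, 7)
  expect_equal(c(h1$lower, h1$upper), c(7, 7))
  expect_equal(hl_median_ci(-5:5)$estimate, 0)
  # agrees with the reference signed-rank implementation
  set.seed(5)
  x <- rnorm(25, 10)
  wt <- wilcox.test(x, conf.int = TRUE, conf.level = 0.95, exact = TRUE,
                    correct = FALSE)
  h2 <- hl_median_ci(x)
  expect_equal(h2$estimate, unname(wt$estimate), tolerance = 1e-10)
  expect_equal(c(h2$lower, h2$upper), as.numeric(wt$conf.int),
               tolerance = 1e-10)
  expect_error(hl_median_ci(numeric(0)), "empty")
})

test_that("Hodges-Lehmann interval covers the median at its nominal rate", {
  hits <- vapply(1:500, function(s) {
    x <- gen_gaussian(30, mean = 3, seed = 4000 + s)
    h <- hl_median_ci(x)
    h$lower <= 3 && 3 <= h$upper
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("Theil regression recovers lines and resists gross outliers", {
  x <- 0:10
  f <- theil_regression(x, 2 * x + 1)
  expect_equal(f$beta, 2)
  expect_equal(f$alpha, 1)
  expect_equal(f$rho_s, 1)
  y <- 2 * x + 1; y[6] <- 500
  expect_equal(theil_regression(x, y)$beta, 2)
  expect_equal(theil_regression(x, rev(x))$rho_s, -1)
  expect_error(theil_regression(rep(1, 5), 1:5), "identical")
})

test_that("Theil slope is consistent under Cauchy noise", {
  beta_hat <- vapply(1:200, function(s) {
    x <- seq_len(50)
    y <- 3 * x + gen_cauchy(50, scale = 2, seed = 6000 + s)
    theil_regression(x, y)$beta
  }, numeric(1))
  expect_lt(abs(median(beta_hat) - 3) / 3, 0.05)
})

test_that("Jarque-Bera matches hand moments and its null behavior", {
  jb <- jarque_bera(rep(c(-1, 1), 4))
  expect_equal(jb$statistic, 8 / 6 * (0 + (1 - 3)^2 / 4))
  expect_equal(jb$skewness, 0)
  expect_equal(jb$kurtosis, 1)
  # type-I error near nominal on Gaussian data
  rej <- vapply(1:200, function(s)
    jarque_bera(gen_gaussian(1000, seed = 8000 + s))$p < 0.05, logical(1))
  expect_gte(mean(rej), 0.02 - 1e-9)
  expect_lte(mean(rej), 0.09)
  # overwhelming power against heavy tails
  rej_c <- vapply(1:100, function(s)
    jarque_bera(gen_cauchy(1000, seed = 9000 + s))$p < 0.05, logical(1))
  expect_gte(mean(rej_c), 0.95)
  expect_error(jarque_bera(rep(2, 10)), "variance")
})

test_that("Smirnov test separates disjoint samples and accepts identity", {
  s <- smirnov_two_sample(1:20, 1:20)
  expect_equal(s$D, 0)
  expect_equal(s$p, 1)
  s2 <- smirnov_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(s2$D, 1)
  expect_error(smirnov_two_sample(numeric(0), 1:3), "empty")
})
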