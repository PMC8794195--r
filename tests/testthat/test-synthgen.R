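test_that("uniform generator matches its closed-form law", {
  x <- gen_uniform(1e5, 0, 1, seed = 11)
  expect_true(all(x >= 0 & x <= 1))
  expect_lt(abs(mean(x) - 0.5), 0.01)
  # Kolmogorov distance of the empirical CDF to the uniform CDF
  y <- sort(gen_uniform(1e4, 0, 1, seed = 12))
  dks <- max(abs(y - (seq_along(y) - 0.5) / length(y))) + 0.5 / length(y)
  expect_lt(dks, 0.02)
  expect_error(gen_uniform(10, a = 1, b = 1), "a < b")
  expect_error(gen_uniform(10, a = 2, b = 1), "a < b")
})

test_that("generators are reproducible and seed-isolated", {
  expect_identical(gen_uniform(50, seed = 5), gen_uniform(50, seed = 5))
  expect_identical(gen_gaussian(51, seed = 5), gen_gaussian(51, seed = 5))
  expect_identical(gen_cauchy(50, seed = 5), gen_cauchy(50, seed = 5))
  expect_false(identical(gen_gaussian(50, seed = 5),
                         gen_gaussian(50, seed = 6)))
  # a seeded call must not disturb the ambient RNG stream
  set.seed(99); a <- rnorm(3)
  set.seed(99); invisible(gen_gaussian(100, seed = 1)); b <- rnorm(3)
  expect_identical(a, b)
})

test_that("Box-Muller transform evaluates both branches correctly", {
  z <- box_muller(0.25, exp(-0.5))   # sqrt(-2 log r2) = 1, angle = pi/2
  expect_equal(z[1], 1.0)
  expect_equal(z[2], 0.0, tolerance = 1e-15)
  x <- gen_gaussian(1e5, 0, 1, seed = 21)
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(var(x) - 1), 0.03)
  # location-scale: N(5, 2^2) is the affine image of the N(0, 1) stream
  expect_equal(gen_gaussian(101, 5, 2, seed = 8),
               5 + 2 * gen_gaussian(101, 0, 1, seed = 8))
  expect_error(gen_gaussian(10, sd = 0), "positive")
})

test_that("Brownian walk accumulates an exact Gaussian stream", {
  b <- gen_brownian(500, seed = 31)
  expect_identical(b[1], 0)
  expect_equal(diff(b), gen_gaussian(499, seed = 31))
  expect_identical(gen_brownian(100, sd = 0, seed = 1), numeric(100))
  expect_error(gen_brownian(1), "at least 2")
  # Var(b_n) = n * sigma^2 for a unit-Gaussian walk
  n <- 1e4
  finals <- vapply(1:200, function(s) gen_brownian(n, seed = 1000 + s)[n],
                   numeric(1))
  expect_lt(abs(var(finals) / (n - 1) - 1), 0.15)
})

test_that("Cauchy generator matches the closed-form quantiles", {
  expect_equal(cauchy_quantile(0.5, location = 3, scale = 2), 3)
  expect_equal(cauchy_quantile(0.975, 0, 1), 12.706, tolerance = 5e-5)
  x <- gen_cauchy(1e4, location = 2, scale = 1, seed = 41)
  expect_lt(abs(median(x) - 2), 0.1)
  expect_error(gen_cauchy(10, scale = 0), "positive")
})

test_that("hospital simulator conserves patients and honors its artifacts", {
  cfg <- hospital_config(days = 600, lag_mean = 20,
                         inject_newyear_spike = TRUE,
                         inject_gap = c(28, 9))
  sim <- simulate_hospital(cfg, seed = 7)
  s <- sim$series
  expect_identical(which(is.na(s$inp)), 29:37)       # 9 consecutive gaps
  expect_true(any(s$adm > 900, na.rm = TRUE))         # impossible spikes
  clean <- !is.na(s$inp) & c(FALSE, !is.na(s$inp[-nrow(s)])) &
    s$adm <= attr(s, "beds") & s$dis <= attr(s, "beds")
  clean[1] <- FALSE
  d_inp <- c(NA, diff(s$inp))
  expect_true(all((d_inp == s$adm - s$dis)[clean], na.rm = TRUE))
  expect_true(all(s$inp >= 0 & s$inp <= attr(s, "beds"), na.rm = TRUE))
  # byte-for-byte reproducibility through the serialized CSV
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_panel_csv(simulate_hospital(cfg, seed = 7)$series, f1)
  write_panel_csv(simulate_hospital(cfg, seed = 7)$series, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("zero lag pins the census; DDiAd variance shrinks with the lag", {
  cfg0 <- hospital_config(days = 300, lag_mean = 0)
  s0 <- simulate_hospital(cfg0, seed = 5)$series
  expect_true(all(s0$inp == s0$inp[1]))
  expect_true(all(s0$adm - s0$dis == 0))
  vdd <- sapply(c(0, 2, 10), function(m) {
    mean(sapply(1:20, function(s) {
      p <- simulate_hospital(hospital_config(days = 300, lag_mean = m),
                             seed = 100 + s)$series
      var(p$adm - p$dis)
    }))
  })
  expect_identical(vdd[1], 0)
  expect_true(all(diff(vdd) > 0))
})

test_that("the default configuration reproduces the study's structure", {
  sim <- simulate_hospital(hospital_config(), seed = 2)
  expect_identical(nrow(sim$series), 1329L)
  expect_identical(attr(sim$series, "beds"), 192L)
  ds_inp <- sevcik_dimension(sim$series$inp)$Ds
  ds_dd <- sevcik_dimension(ddiad(sim$series))$Ds
  w <- calibrate("white", 1329, 50, seed = 3)
  b <- calibrate("brownian", 1329, 50, seed = 4)
  # census inside the Brownian band, difference series inside the white band
  expect_false(compare_dimensions(list(mean = ds_inp, var = 1e-6), b)$significant)
  expect_false(compare_dimensions(list(mean = ds_dd, var = 1e-6), w)$significant)
  expect_true(compare_dimensions(list(mean = ds_inp, var = 1e-6), w)$significant)
})

test_that("infeasible configurations are rejected", {
  expect_error(hospital_config(beds = 100, target_census = 150),
               "infeasible")
  expect_error(hospital_config(days = 100, inject_gap = c(95, 9)))
})
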