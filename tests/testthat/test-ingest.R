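test_that("canonical CSV round-trips and validates", {
  p <- make_clean_panel(days = 10)
  f <- tempfile(fileext = ".csv")
  write_panel_csv(p, f)
  q <- load_panel(f, beds = attr(p, "beds"))
  expect_identical(nrow(q), 10L)
  expect_identical(q$adm, p$adm)
  expect_identical(q$dis, p$dis)
  expect_identical(q$inp, p$inp)

  # missing cells survive the round trip as missing
  p2 <- make_clean_panel(days = 12)
  p2$inp[5] <- NA
  write_panel_csv(p2, f)
  expect_true(is.na(load_panel(f)$inp[5]))

  writeLines(c("day,adm,dis,inp", "0,1,2,150", "1,3,1,abc"), f)
  expect_error(load_panel(f), "row 2")
  writeLines(c("day,adm,dis,inp", "0,1,2,150", "2,3,1,151"), f)
  expect_error(load_panel(f), "increase by 1")
  writeLines(c("day,adm,dis,inp", "0,1,2,150", "0,3,1,151"), f)
  expect_error(load_panel(f), "duplicate")
  writeLines(c("day,adm,dis,inp", "0,1,2,150.5"), f)
  expect_error(load_panel(f), "non-integer")
})

test_that("year-boundary repair averages the flanking days", {
  p <- make_clean_panel(days = 30)
  p$adm[10] <- 900L
  flank_mean <- (p$adm[9] + p$adm[11]) / 2
  q <- fix_new_year(p)
  expect_equal(q$adm[10], flank_mean)
  expect_true(attr(q, "flags")$newyear_corrected[10])
  expect_equal(q$adm[-10], as.numeric(p$adm[-10]))  # untouched elsewhere
  lg <- attr(q, "cleaning_log")
  expect_identical(lg$rule, "newyear")
  expect_equal(lg$old, 900)

  # spike of 900 between flanks 148 and 152 -> 150
  p2 <- make_clean_panel(days = 5)
  p2$inp[1:5] <- c(140L, 148L, 900L, 152L, 151L)
  expect_equal(fix_new_year(p2)$inp[3], 150)

  # no impossible value -> identity
  expect_identical(fix_new_year(make_clean_panel(days = 20)),
                   make_clean_panel(days = 20))

  # adjacent spikes: the rule cannot apply
  p3 <- make_clean_panel(days = 10)
  p3$dis[4:5] <- c(950L, 960L)
  expect_error(fix_new_year(p3), "adjacent")

  p4 <- make_clean_panel(days = 10)
  p4$adm[1] <- 950L
  expect_error(fix_new_year(p4), "boundary")
})

test_that("gap bridging applies the constant daily change cumulatively", {
  p <- make_clean_panel(days = 20)
  p$inp[5:13] <- NA            # 9-day gap, days 4..12
  p$inp[4] <- 100L; p$inp[14] <- 109L
  q <- fill_gap(p, gap_start = 4, gap_len = 9, columns = "inp")
  expect_equal(q$inp[5:13], 101:109)
  expect_true(all(attr(q, "flags")$gap_filled[5:13]))
  expect_equal(q$inp[-(5:13)], as.numeric(p$inp[-(5:13)]))

  # zero slope: constant fill
  p2 <- make_clean_panel(days = 10)
  p2$inp[4:6] <- NA; p2$inp[3] <- 120L; p2$inp[7] <- 120L
  expect_equal(fill_gap(p2, 3, 3, "inp")$inp[4:6], rep(120, 3))

  # non-integer bridges are kept as reals so telescoping stays exact
  p3 <- make_clean_panel(days = 10)
  p3$inp[4:5] <- NA; p3$inp[3] <- 100L; p3$inp[6] <- 101L
  expect_equal(fill_gap(p3, 3, 2, "inp")$inp[4:5], c(100.5, 101))

  p4 <- make_clean_panel(days = 10)
  p4$inp[1:3] <- NA
  expect_error(fill_gap(p4, 0, 3, "inp"), "start")
})

test_that("cleaning is idempotent and auto-detects gaps", {
  cfg <- hospital_config(days = 700, lag_mean = 20,
                         inject_newyear_spike = TRUE,
                         inject_gap = c(28, 9))
  raw <- simulate_hospital(cfg, seed = 9)$series
  once <- fill_gap(fix_new_year(raw))
  twice <- fill_gap(fix_new_year(once))
  expect_equal(as.data.frame(twice), as.data.frame(once))
  expect_false(anyNA(once$inp))
  f <- tempfile(fileext = ".json")
  write_cleaning_log(once, f)
  lg <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_true(all(c("newyear", "gap_fill") %in% lg$rule))
})

test_that("difference series follow the delta-y convention", {
  expect_equal(daily_diff(c(5, 7, 4)), c(0, 2, -3))
  expect_equal(daily_diff(rep(3, 6)), rep(0, 6))
  y <- cumsum(rnorm(50))
  expect_equal(sum(daily_diff(y)), y[50] - y[1])   # telescoping
  expect_error(daily_diff(c(1, NA, 3)), "missing")
})

test_that("DDiAd and the reconstructed walk recover the census exactly", {
  p <- make_clean_panel(days = 300)
  d <- ddiad(p)
  expect_identical(d[1:2], (p$adm - p$dis)[1:2])
  xi <- reconstruct_walk(d)
  expect_identical(xi[1], 0)
  expect_equal(xi + p$inp[1], p$inp)               # conservation identity
  expect_equal(reconstruct_walk(c(0, 1, -1, 2)), c(0, 1, 0, 2))
  expect_equal(daily_diff(reconstruct_walk(c(0, 4, -2, 1)))[-1],
               c(4, -2, 1))                        # diff o walk = identity
  expect_error(reconstruct_walk(numeric(0)), "empty")
})

test_that("mean length of stay is the per-day patient mean, NA when empty", {
  out <- mean_los(list(c(10, 10, 10), c(2, 4), numeric(0)))
  expect_equal(out, c(10, 3, NA))
  expect_error(mean_los(list(c(2, -1))), "negative")
})

test_that("occupancy summary reports medians and ranges as percent of beds", {
  p <- make_clean_panel(days = 50)
  p$inp[] <- 150L
  o <- occupancy_stats(p)
  expect_equal(o$median, 150)
  expect_equal(round(o$pct_median, 1), 78.1)
  p2 <- make_clean_panel(days = 400)
  p2$inp <- as.integer(round(seq(102, 187, length.out = 400)))
  o2 <- occupancy_stats(p2)
  expect_equal(round(o2$pct_min, 1), 53.1)
  expect_equal(round(o2$pct_max, 1), 97.4)
})
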