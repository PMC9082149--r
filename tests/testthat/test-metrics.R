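test_that("pearson_r matches direct evaluation of the formula", {
  expect_equal(pearson_r(c(0, 1, 2, 3), c(0, 1, 2, 5)),
               pearson_direct(c(0, 1, 2, 3), c(0, 1, 2, 5)),
               tolerance = 1e-12)
  x <- c(1, 5, 2, 8)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(50)
    b <- rnorm(50)
    expect_equal(pearson_r(a, b), pearson_direct(a, b), tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:3, 1:4), "unequal")
})

test_that("pearson_r is invariant under positive affine maps", {
  set.seed(42)
  a <- rnorm(60)
  b <- rnorm(60)
  expect_equal(pearson_r(2.5 * a + 3, b), pearson_r(a, b), tolerance = 1e-12)
  expect_equal(pearson_r(a, 0.1 * b - 7), pearson_r(a, b), tolerance = 1e-12)
})

test_that("rmse matches its closed form and is translation-covariant", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(0, 3), c(4, 3)), sqrt(8))
  set.seed(43)
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(rmse(a + 5, b + 5), rmse(a, b), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "unequal")
})

test_that("dtw of identical signals is zero with a diagonal path", {
  x <- sin(1:20 / 3)
  d <- dtw(x, x)
  expect_equal(d$distance, 0)
  expect_equal(d$path$i, 1:20)
  expect_equal(d$path$j, 1:20)
})

test_that("dtw base cases and path validity", {
  d1 <- dtw(3.5, 1.5)
  expect_equal(d1$distance, 2)
  d <- dtw(c(0, 1, 0), c(0, 0, 1))
  expect_equal(d$distance, dtw_brute(c(0, 1, 0), c(0, 0, 1)))
  # path steps are monotone and anchored
  steps <- cbind(diff(d$path$i), diff(d$path$j))
  expect_true(all(steps %in% 0:1), all(rowSums(steps) >= 1))
  expect_equal(unlist(d$path[1, ]), c(i = 1, j = 1))
  expect_equal(unlist(d$path[nrow(d$path), ]), c(i = 3, j = 3))
  expect_error(dtw(numeric(0), numeric(0)), "empty")
})

test_that("dtw equals exhaustive path enumeration on random pairs", {
  set.seed(44)
  for (trial in 1:100) {
    m <- sample(2:8, 1)
    a <- rnorm(m)
    b <- rnorm(m)
    expect_equal(dtw(a, b, return_path = FALSE)$distance, dtw_brute(a, b),
                 tolerance = 1e-10, info = paste("trial", trial))
  }
})

test_that("dtw is symmetric and the amplitude-only cost is available", {
  set.seed(45)
  for (i in 1:10) {
    a <- rnorm(20)
    b <- rnorm(20)
    expect_equal(dtw(a, b, return_path = FALSE)$distance,
                 dtw(b, a, return_path = FALSE)$distance, tolerance = 1e-10)
  }
  a <- rnorm(7)   # exhaustive oracle is only tractable at small m
  b <- rnorm(7)
  amp <- dtw(a, b, index_cost = FALSE, return_path = FALSE)$distance
  expect_equal(amp, dtw_brute(a, b, index_cost = FALSE), tolerance = 1e-10)
  expect_lte(amp, dtw(a, b, return_path = FALSE)$distance)
})

test_that("the banded dtw equals the full dtw on medium signals", {
  set.seed(46)
  m <- 500
  a <- sin(1:m / 10) + rnorm(m, sd = 0.1)
  b <- sin((1:m + 4) / 10) + rnorm(m, sd = 0.1)
  full <- dtw(a, b, return_path = FALSE)$distance
  banded <- dtw(a, b, band_radius = 50, return_path = FALSE)$distance
  expect_equal(banded, full, tolerance = 1e-10)
})

test_that("dtw_per_second divides by the duration", {
  expect_equal(dtw_per_second(533.218, 228), 533.218 / 228)
  expect_equal(dtw_per_second(0, 100), 0)
  expect_equal(dtw_per_second(10, 5), 2)
  expect_error(dtw_per_second(1, 0), "positive")
})

test_that("cross-correlation alignment recovers integer delays exactly", {
  fs <- 125
  t <- seq(0, 8, by = 1 / fs)
  ref <- sin(2 * pi * 1.3 * t) + 0.3 * sin(2 * pi * 3.1 * t)
  for (d in c(-7, -5, 0, 3, 5, 10)) {
    n <- length(ref)
    rec <- if (d >= 0) c(rep(ref[1], d), ref[1:(n - d)])
           else c(ref[(1 - d):n], rep(ref[n], -d))
    al <- xcorr_align(ref, rec, fs, window_ms = 80)
    expect_identical(al$lag, as.integer(d), info = paste("delay", d))
    expect_equal(pearson_r(al$ref, al$rec), 1, tolerance = 1e-9)
    expect_lt(rmse(al$ref, al$rec), 1e-9)
  }
})

test_that("lags beyond the window are clipped to the window bound", {
  fs <- 125
  t <- seq(0, 8, by = 1 / fs)
  ref <- sin(2 * pi * 1 * t)   # slow enough that xcorr is unimodal
  d <- 15                      # 120 ms > the 80 ms window
  n <- length(ref)
  rec <- c(rep(0, d), ref[1:(n - d)])
  al <- xcorr_align(ref, rec, fs, window_ms = 80)
  expect_equal(abs(al$lag), 10)
  expect_lt(pearson_r(al$ref, al$rec), 1)
})

test_that("alignment never reduces the correlation and validates input", {
  set.seed(47)
  fs <- 125
  ref <- as.numeric(stats::filter(rnorm(1000), rep(0.2, 5), sides = 2))
  ref[is.na(ref)] <- 0
  rec <- ref + rnorm(1000, sd = 0.2)
  al <- xcorr_align(ref, rec, fs)
  expect_gte(al$correlation, pearson_r(ref, rec))
  expect_error(xcorr_align(ref[1:5], rec[1:5], fs, window_ms = 80),
               "window")
})

test_that("evaluate_reconstruction on identical segments is perfect", {
  set.seed(48)
  segs <- matrix(rnorm(4 * 125), 4, 125)
  ev <- evaluate_reconstruction(segs, segs, fs = 125, segment_s = 1)
  expect_true(all(tidy(ev)$r == 1))
  expect_true(all(tidy(ev)$rmse == 0))
  expect_true(all(tidy(ev)$d == 0))
  expect_equal(ev$stitched$r_s, 1)
  expect_equal(ev$stitched$rmse_s, 0)
  expect_equal(ev$stitched$d_s, 0)
})

test_that("per-segment aggregation uses the two-value mean and sd", {
  # construct two 1-s segments with known per-segment correlations
  set.seed(49)
  ref <- matrix(rnorm(2 * 125), 2, 125)
  rec <- ref
  # segment 1: r = 0.5 by mixing in orthogonalized noise
  e <- rnorm(125)
  e <- e - mean(e)
  r1 <- ref[1, ] - mean(ref[1, ])
  e <- e - sum(e * r1) / sum(r1^2) * r1
  alpha <- sqrt(3) * sqrt(sum(r1^2) / sum(e^2))   # gives cor = 0.5
  rec[1, ] <- r1 + alpha * e
  stopifnot(abs(pearson_r(ref[1, ], rec[1, ]) - 0.5) < 1e-10)
  ev <- evaluate_reconstruction(ref, rec, fs = 125, segment_s = 1)
  g <- glance(ev)
  expect_equal(g$r_mean, mean(c(0.5, 1)), tolerance = 1e-10)
  expect_equal(g$r_sd, stats::sd(c(0.5, 1)), tolerance = 1e-10)
  expect_equal(g$n_segments, 2)
})

test_that("a uniform delay is repaired by Alignment II in the report", {
  fs <- 125
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  base <- sin(2 * pi * 1.1 * t) + 0.4 * sin(2 * pi * 2.3 * t)
  d <- 3
  delayed <- c(rep(base[1], d), base[1:(length(base) - d)])
  cut <- function(x) matrix(x, ncol = fs, byrow = TRUE)
  ev <- evaluate_reconstruction(cut(base), cut(delayed), fs, segment_s = 1)
  expect_true(all(tidy(ev)$r < 1))
  expect_true(all(tidy(ev)$lag == d))
  expect_true(all(tidy(ev)$r_a > 0.9999))
  expect_true(all(tidy(ev)$rmse_a < 1e-6))
  expect_equal(ev$stitched$lag_s, 3L)
  expect_gt(ev$stitched$r_sa, ev$stitched$r_s)
})

test_that("pooling across records aggregates segments and stitched rows", {
  set.seed(50)
  mk <- function() {
    ref <- matrix(rnorm(3 * 125), 3, 125)
    evaluate_reconstruction(ref, ref + rnorm(length(ref), sd = 0.1),
                            fs = 125, segment_s = 1)
  }
  evs <- list(mk(), mk())
  pooled <- pool_evals(evs)
  expect_equal(pooled$n_records, 2)
  expect_equal(pooled$n_segments, 6)
  expect_equal(pooled$r_mean,
               mean(c(tidy(evs[[1]])$r, tidy(evs[[2]])$r)))
  expect_equal(pooled$r_s_mean,
               mean(c(evs[[1]]$stitched$r_s, evs[[2]]$stitched$r_s)))
})
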