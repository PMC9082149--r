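test_that("a jitter-free 60 bpm minute contains exactly 60 beats", {
  s <- generate_record(synthetic_config(duration_s = 60, heart_rate_bpm = 60,
                                        rr_jitter_sd_s = 0, seed = 1))
  expect_length(s$truth$r_peaks, 60)
  expect_equal(unique(diff(s$truth$r_peaks)), 125)
})

test_that("true systolic peaks sit exactly PAT samples after their R peak", {
  for (pat in c(0, 0.2, 0.31)) {
    s <- generate_record(synthetic_config(duration_s = 30, pat_s = pat,
                                          seed = 2))
    expect_equal(s$truth$systolic_peaks - s$truth$r_peaks,
                 rep(round(pat * 125), length(s$truth$r_peaks)))
  }
})

test_that("generation is seed-deterministic", {
  cfg <- synthetic_config(duration_s = 20, noise_sd = 0.05, seed = 9)
  a <- generate_record(cfg)
  b <- generate_record(cfg)
  expect_identical(a$record$ecg, b$record$ecg)
  expect_identical(a$record$ppg, b$record$ppg)
  cfg2 <- cfg
  cfg2$seed <- 10L
  c2 <- generate_record(cfg2)
  expect_false(identical(a$record$ecg, c2$record$ecg))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_record(synthetic_config(duration_s = 10, seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("records satisfy the container invariants", {
  s <- generate_record(synthetic_config(duration_s = 45, noise_sd = 0.03,
                                        heart_rate_bpm = 80, seed = 5))
  expect_true(all(is.finite(s$record$ecg)))
  expect_length(s$record$ecg, length(s$record$ppg))
  expect_true(all(diff(s$truth$r_peaks) > 0))
  expect_true(all(diff(s$truth$systolic_peaks) > 0))
  expect_lte(max(s$truth$systolic_peaks), length(s$record$ppg))
})

test_that("cohorts are reproducible with distinct subjects", {
  a <- make_cohort(3, base = synthetic_config(duration_s = 15), seed = 0)
  b <- make_cohort(3, base = synthetic_config(duration_s = 15), seed = 0)
  expect_length(a, 3)
  expect_identical(purrr::map(a, ~.x$record$ecg),
                   purrr::map(b, ~.x$record$ecg))
  expect_false(identical(a[[1]]$record$ecg, a[[2]]$record$ecg))
  expect_false(a[[1]]$config$heart_rate_bpm == a[[2]]$config$heart_rate_bpm)
})

test_that("degenerate variation ranges share parameters but not noise", {
  a <- make_cohort(2, base = synthetic_config(duration_s = 15,
                                              noise_sd = 0.05),
                   variation = list(heart_rate_bpm = c(70, 70)), seed = 1)
  expect_equal(a[[1]]$config$heart_rate_bpm, 70)
  expect_equal(a[[2]]$config$heart_rate_bpm, 70)
  expect_false(identical(a[[1]]$record$ecg, a[[2]]$record$ecg))
  expect_error(make_cohort(2, variation = list(heart_rate_bpm = c(80, 60))),
               "range")
})
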