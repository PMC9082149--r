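fs <- 125

test_that("band-pass rejects DC, passes 10 Hz, attenuates 50 Hz", {
  t <- seq(0, 10, by = 1 / fs)
  spec <- ecg_filter_spec()

  dc <- rep(5, length(t))
  expect_lt(max(abs(bandpass(dc, fs, spec))), 0.01 * 5)

  x10 <- sin(2 * pi * 10 * t)
  expect_lt(abs(rms(bandpass(x10, fs, spec)) / rms(x10) - 1), 0.10)

  x50 <- sin(2 * pi * 50 * t)
  expect_lt(rms(bandpass(x50, fs, spec)) / rms(x50),
            10^(-spec$stopband_atten_db / 20) * 1.5)
})

test_that("band-pass is idempotent within 5% on in-band content", {
  t <- seq(0, 8, by = 1 / fs)
  x <- sin(2 * pi * 7 * t) + 0.5 * sin(2 * pi * 13 * t)
  once <- bandpass(x, fs, ecg_filter_spec())
  twice <- bandpass(once, fs, ecg_filter_spec())
  expect_lt(abs(rms(twice) / rms(once) - 1), 0.05)
})

test_that("band-pass validates its configuration and input", {
  expect_error(filter_spec(0.5, 0.2), "band_low")
  expect_error(bandpass(rnorm(500), 30, filter_spec(0.5, 20)), "Nyquist")
  expect_error(bandpass(rnorm(10), fs, ecg_filter_spec()), "too short")
})

test_that("R peaks are recovered exactly on clean synthetic ECG", {
  s <- generate_record(synthetic_config(duration_s = 30, seed = 21))
  ecg_f <- bandpass(s$record$ecg, fs, ecg_filter_spec())
  det <- detect_r_peaks(ecg_f, fs)
  m <- match_peaks(s$truth$r_peaks, det, tol = round(0.040 * fs))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$precision, 1)
  expect_true(all(diff(det) >= round(0.2 * fs)))
})

test_that("R-peak detection stays above 95% at 20 dB SNR", {
  clean <- generate_record(synthetic_config(duration_s = 60, seed = 22))
  noise_sd <- rms(clean$record$ecg) / 10   # 20 dB down
  s <- generate_record(synthetic_config(duration_s = 60,
                                        noise_sd = noise_sd, seed = 22))
  det <- detect_r_peaks(bandpass(s$record$ecg, fs, ecg_filter_spec()), fs)
  m <- match_peaks(s$truth$r_peaks, det, tol = round(0.040 * fs))
  expect_gte(m$sensitivity, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("systolic peaks are recovered on clean and noisy PPG", {
  s <- generate_record(synthetic_config(duration_s = 30, seed = 23))
  ppg_f <- bandpass(s$record$ppg, fs, ppg_filter_spec())
  det <- detect_systolic_peaks(ppg_f, fs)
  m <- match_peaks(s$truth$systolic_peaks, det, tol = round(0.060 * fs))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$precision, 1)

  clean_rms <- rms(s$record$ppg - mean(s$record$ppg))
  sn <- generate_record(synthetic_config(duration_s = 60,
                                         noise_sd = clean_rms / 10,
                                         seed = 24))
  detn <- detect_systolic_peaks(bandpass(sn$record$ppg, fs,
                                         ppg_filter_spec()), fs)
  mn <- match_peaks(sn$truth$systolic_peaks, detn, tol = round(0.060 * fs))
  expect_gte(mn$sensitivity, 0.90)
  expect_gte(mn$precision, 0.90)
})

test_that("degenerate detector inputs behave as specified", {
  expect_identical(detect_r_peaks(rep(0, 10 * fs), fs), integer(0))
  expect_identical(detect_systolic_peaks(rep(0, 10 * fs), fs), integer(0))
  expect_error(detect_r_peaks(rnorm(fs), fs), "2 s")
  expect_error(detect_systolic_peaks(rnorm(fs), fs), "2 s")
})

test_that("normalize_ppg maps to [0,1] and is affine-invariant", {
  expect_equal(normalize_ppg(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 0.5, 1)
  expect_equal(normalize_ppg(x), x)
  set.seed(31)
  y <- rnorm(100)
  expect_equal(normalize_ppg(3.7 * y + 11), normalize_ppg(y))
  expect_error(normalize_ppg(rep(5, 3)), "constant")
})

test_that("Alignment I removes a known pulse arrival time exactly", {
  s <- generate_record(synthetic_config(duration_s = 30, pat_s = 0.2,
                                        seed = 25))
  ap <- align_pair(s$record$ecg, s$record$ppg, fs, s$truth)
  expect_identical(ap$applied_lag, 25L)
  # the anchor beat's systolic peak now coincides with its R peak
  corr <- beat_correspondence(s$truth$r_peaks, s$truth$systolic_peaks)
  anchor <- corr[corr$beat >= 3, ][1, ]
  expect_identical(anchor$sys_idx - ap$applied_lag, anchor$r_idx)
  expect_length(ap$ecg, length(ap$ppg))
  expect_equal(range(ap$ppg), c(0, 1))
})

test_that("PAT = 0 yields zero lag and untouched support", {
  s <- generate_record(synthetic_config(duration_s = 30, pat_s = 0,
                                        seed = 26))
  ap <- align_pair(s$record$ecg, s$record$ppg, fs, s$truth,
                   normalize = FALSE)
  expect_identical(ap$applied_lag, 0L)
  expect_identical(ap$ecg, s$record$ecg)
  expect_identical(ap$ppg, s$record$ppg)
})

test_that("alignment preconditions are enforced", {
  s <- generate_record(synthetic_config(duration_s = 30, seed = 27))
  two <- list(r_peaks = s$truth$r_peaks[1:2],
              systolic_peaks = s$truth$systolic_peaks[1:2])
  expect_error(align_pair(s$record$ecg, s$record$ppg, fs, two),
               "3 beat correspondences")
  # anchor beat without a correspondence: skip forward with a warning
  gappy <- list(r_peaks = s$truth$r_peaks,
                systolic_peaks = s$truth$systolic_peaks[-3])
  expect_warning(ap <- align_pair(s$record$ecg, s$record$ppg, fs, gappy),
                 "anchor beat")
  expect_identical(ap$applied_lag, 25L)
})

test_that("re-detection after alignment finds coincident peaks", {
  s <- generate_record(synthetic_config(duration_s = 60, seed = 28))
  ap <- preprocess_record(s$record)
  rp <- detect_r_peaks(ap$ecg, fs)
  sp <- detect_systolic_peaks(ap$ppg, fs)
  corr <- beat_correspondence(rp, sort(unique(c(rp, sp))))
  # offsets between each systolic peak and its R peak, post alignment
  offs <- purrr::map_dbl(rp[-length(rp)], function(r) {
    nxt <- sp[sp >= r - 2]
    if (length(nxt) == 0) return(NA_real_)
    nxt[1] - r
  })
  expect_lte(abs(stats::median(offs, na.rm = TRUE)), 2)
})
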