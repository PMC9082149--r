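#' Configuration for the synthetic paired-beat generator
#'
#' Describes a quasi-periodic paired ECG/PPG subject. Each heartbeat places
#' five Gaussian components (P, Q, R, S, T) on the ECG and two (systolic,
#' diastolic) on the PPG; the PPG components are delayed by the pulse
#' arrival time so that every true systolic peak sits exactly
#' `round(pat_s * fs)` samples after its R peak.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Record length, seconds.
#' @param heart_rate_bpm Mean heart rate, beats per minute.
#' @param rr_jitter_sd_s Standard deviation of the per-beat RR perturbation,
#'   seconds (0.02 s mimics resting sinus variability).
#' @param pat_s Pulse arrival time: PPG delay relative to the R peak, seconds.
#' @param ecg_wave_params Data frame with columns `wave, amp, offset, width`
#'   (mV, s, s) for the P, Q, R, S, T Gaussian components, offsets relative
#'   to the R peak.
#' @param ppg_wave_params Data frame with columns `wave, amp, offset, width`
#'   for the systolic and diastolic components, offsets relative to the
#'   (already PAT-delayed) systolic peak.
#' @param noise_sd Standard deviation of additive white Gaussian noise, in
#'   each channel's amplitude units (band-limited noise available via
#'   `noise_band_hz`).
#' @param noise_band_hz Optional length-2 numeric: low-pass corner per
#'   channel applied to the noise before adding (NULL = white).
#' @param ppg_scale,ppg_offset Affine map applied to the unit-amplitude PPG
#'   so stored PPG is on an arbitrary positive scale.
#' @param seed Integer seed; identical seeds give identical records.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(fs = 125, duration_s = 300,
                             heart_rate_bpm = 60, rr_jitter_sd_s = 0.02,
                             pat_s = 0.2,
                             ecg_wave_params = default_ecg_waves(),
                             ppg_wave_params = default_ppg_waves(),
                             noise_sd = 0, noise_band_hz = NULL,
                             ppg_scale = 1.8, ppg_offset = 0.4,
                             seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, heart_rate_bpm > 0, pat_s >= 0,
            rr_jitter_sd_s >= 0, noise_sd >= 0,
            all(ecg_wave_params$width > 0), all(ppg_wave_params$width > 0))
  structure(
    list(fs = fs, duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
         rr_jitter_sd_s = rr_jitter_sd_s, pat_s = pat_s,
         ecg_wave_params = ecg_wave_params,
         ppg_wave_params = ppg_wave_params,
         noise_sd = noise_sd, noise_band_hz = noise_band_hz,
         ppg_scale = ppg_scale, ppg_offset = ppg_offset,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Default ECG Gaussian wave parameters
#'
#' Amplitudes in mV, offsets (relative to the R peak) and Gaussian widths in
#' seconds; values give a lead-II-like beat (QRS ~100 ms, upright T).
#' @return A tibble with columns `wave, amp, offset, width`.
#' @export
default_ecg_waves <- function() {
  tibble::tibble(
    wave = c("P", "Q", "R", "S", "T"),
    amp = c(0.15, -0.15, 1.20, -0.25, 0.35),
    offset = c(-0.20, -0.05, 0.00, 0.05, 0.28),
    width = c(0.030, 0.015, 0.025, 0.020, 0.070))
}

#' Default PPG Gaussian wave parameters
#'
#' Unit systolic wave plus a smaller, later diastolic wave; offsets relative
#' to the systolic peak (which itself lags the R peak by the pulse arrival
#' time).
#' @return A tibble with columns `wave, amp, offset, width`.
#' @export
default_ppg_waves <- function() {
  tibble::tibble(
    wave = c("systolic", "diastolic"),
    amp = c(1.00, 0.35),
    offset = c(0.00, 0.28),
    width = c(0.090, 0.120))
}

#' Generate one synthetic paired ECG/PPG record
#'
#' Beat times follow a jittered grid at the configured heart rate; R-peak
#' sample indices are the rounded beat times and each true systolic peak is
#' exactly `round(pat_s * fs)` samples later, so the generator's annotations
#' are exact ground truth for the detectors and for pulse-arrival-time
#' alignment.
#'
#' @param config A [synthetic_config()].
#' @param record_id Identifier for the generated record.
#' @return A list of class `synthetic_record` with elements `record`
#'   ([ecg_record()]), `truth` (list with integer vectors `r_peaks`,
#'   `systolic_peaks`, 1-based sample indices), and `config`.
#' @examples
#' s <- generate_record(synthetic_config(duration_s = 30, seed = 7))
#' length(s$truth$r_peaks)
#' @export
generate_record <- function(config, record_id = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- local_rng(config$seed)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  rr_mean <- 60 / config$heart_rate_bpm
  n_beats_max <- ceiling(config$duration_s / rr_mean) + 10L
  rr <- rr_mean + rng$norm(n_beats_max, sd = config$rr_jitter_sd_s)
  rr <- pmax(rr, 0.3)                     # physiological floor (200 bpm)
  beat_t <- cumsum(c(rr_mean / 2, rr))    # first R half a period in
  beat_t <- beat_t[beat_t < config$duration_s - 1 / fs]

  # snap beat centers to the sample grid so annotations are exact
  # (floor(x + 0.5): round() halves-to-even would warp a regular beat grid)
  r_idx <- pmin(pmax(floor(beat_t * fs + 0.5) + 1L, 1L), n)
  pat_samp <- round(config$pat_s * fs)
  # only emit complete beats: the systolic wave needs support past its peak
  keep <- r_idx + pat_samp + round(0.25 * fs) <= n
  r_idx <- r_idx[keep]
  r_time <- (r_idx - 1) / fs
  sys_idx <- r_idx + pat_samp
  sys_time <- (sys_idx - 1) / fs

  ecg <- gaussian_train(t, r_time, config$ecg_wave_params)
  ppg <- gaussian_train(t, sys_time, config$ppg_wave_params)
  ppg <- ppg * config$ppg_scale + config$ppg_offset

  if (config$noise_sd > 0) {
    ne <- rng$norm(n, sd = config$noise_sd)
    np <- rng$norm(n, sd = config$noise_sd)
    if (!is.null(config$noise_band_hz)) {
      lp <- signal::butter(2, min(config$noise_band_hz[1], fs / 2 * 0.99) /
                                (fs / 2), type = "low")
      ne <- as.numeric(signal::filter(lp, ne))
      np <- as.numeric(signal::filter(lp, np))
    }
    ecg <- ecg + ne
    ppg <- ppg + np
  }

  structure(
    list(record = ecg_record(ecg, ppg, fs = fs, record_id = record_id),
         truth = list(r_peaks = as.integer(r_idx),
                      systolic_peaks = as.integer(sys_idx)),
         config = config),
    class = "synthetic_record")
}

# superposition of Gaussian bumps at each beat center; each bump only
# touches +-5 widths so long records stay O(n)
gaussian_train <- function(t, centers, waves) {
  out <- numeric(length(t))
  dt <- t[2] - t[1]
  for (k in seq_len(nrow(waves))) {
    for (c0 in centers + waves$offset[k]) {
      lo <- max(1L, floor((c0 - 5 * waves$width[k]) / dt) + 1L)
      hi <- min(length(t), ceiling((c0 + 5 * waves$width[k]) / dt) + 1L)
      if (hi < lo) next
      idx <- lo:hi
      out[idx] <- out[idx] +
        waves$amp[k] * exp(-((t[idx] - c0)^2) / (2 * waves$width[k]^2))
    }
  }
  out
}

#' @export
print.synthetic_record <- function(x, ...) {
  print(x$record)
  cat(sprintf("  truth: %d R peaks, PAT = %g s (%d samples)\n",
              length(x$truth$r_peaks), x$config$pat_s,
              round(x$config$pat_s * x$config$fs)))
  invisible(x)
}

#' Generate a reproducible cohort of synthetic subjects
#'
#' Per-record heart rate, pulse arrival time, and wave amplitudes are drawn
#' uniformly from the given ranges with a per-record sub-seed derived from
#' `seed`, so any record can be regenerated independently.
#'
#' @param n_records Number of subjects (>= 1).
#' @param base A [synthetic_config()] supplying all non-varied parameters.
#' @param variation Named list of length-2 numeric ranges; supported names:
#'   `heart_rate_bpm`, `pat_s`, `r_amp`, `noise_sd`.
#' @param seed Integer master seed.
#' @return A list of `synthetic_record` objects named by record id.
#' @export
make_cohort <- function(n_records, base = synthetic_config(),
                        variation = list(heart_rate_bpm = c(55, 95),
                                         pat_s = c(0.15, 0.30)),
                        seed = 1L) {
  stopifnot(n_records >= 1)
  for (v in variation) {
    if (length(v) != 2 || any(!is.finite(v)) || v[2] < v[1]) {
      stop("each variation entry must be a finite range c(min, max)",
           call. = FALSE)
    }
  }
  rng <- local_rng(seed)
  sub_seeds <- rng$int(n_records, max = 2^30)
  purrr::map(seq_len(n_records), function(i) {
    r2 <- local_rng(sub_seeds[i])
    cfg <- base
    draw <- function(name, default) {
      if (!is.null(variation[[name]])) {
        r2$unif(1, variation[[name]][1], variation[[name]][2])
      } else default
    }
    cfg$heart_rate_bpm <- draw("heart_rate_bpm", base$heart_rate_bpm)
    cfg$pat_s <- draw("pat_s", base$pat_s)
    cfg$noise_sd <- draw("noise_sd", base$noise_sd)
    r_amp <- draw("r_amp", NA)
    if (!is.na(r_amp)) {
      cfg$ecg_wave_params$amp[cfg$ecg_wave_params$wave == "R"] <- r_amp
    }
    cfg$seed <- r2$int(1, max = 2^30)
    generate_record(cfg, record_id = sprintf("synthetic_%03d", i))
  }) |>
    rlang::set_names(sprintf("synthetic_%03d", seq_len(n_records)))
}

# Seeded RNG scoped to the generator: does not disturb the caller's
# .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    s
  })
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) {
          if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          }
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      })
      f(...)
    }
  }
  list(
    norm = with_state(function(n, sd = 1) stats::rnorm(n, sd = sd)),
    unif = with_state(function(n, min = 0, max = 1) stats::runif(n, min, max)),
    int = with_state(function(n, max) sample.int(max, n, replace = TRUE))
  )
}
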