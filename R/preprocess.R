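#' Band-pass filter specification
#'
#' Chebyshev type II band-pass realized as a cascade of a fourth-order
#' high-pass and a fourth-order low-pass section, applied zero-phase.
#' Stopband edges sit at `0.5 * band_low` and `1.25 * band_high`.
#'
#' @param band_low,band_high Passband edges, Hz.
#' @param order Order of each Chebyshev II section (default 4).
#' @param stopband_atten_db Stopband attenuation, dB (default 40).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(band_low, band_high, order = 4,
                        stopband_atten_db = 40) {
  if (!(band_low > 0 && band_high > band_low)) {
    stop("need 0 < band_low < band_high", call. = FALSE)
  }
  structure(list(band_low = band_low, band_high = band_high,
                 order = as.integer(order),
                 stopband_atten_db = stopband_atten_db),
            class = "filter_spec")
}

#' Default ECG passband (0.5-20 Hz)
#' @return A [filter_spec()].
#' @export
ecg_filter_spec <- function() filter_spec(0.5, 20)

#' Default PPG passband (0.5-10 Hz)
#' @return A [filter_spec()].
#' @export
ppg_filter_spec <- function() filter_spec(0.5, 10)

#' Zero-phase Chebyshev II band-pass
#'
#' Filters forward and backward (no group delay, so peak indices are
#' preserved across channels) with odd reflective padding at both ends to
#' suppress start-up transients. Output length equals input length.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- fs / 2
  ws_high <- 0.5 * spec$band_low / nyq
  ws_low <- 1.25 * spec$band_high / nyq
  if (spec$band_high >= nyq || ws_low >= 1) {
    stop("band edges must lie below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  if (length(x) <= 3 * spec$order) {
    stop("signal too short to filter (need > ", 3 * spec$order, " samples)",
         call. = FALSE)
  }
  hp <- signal::cheby2(spec$order, spec$stopband_atten_db, ws_high,
                       type = "high")
  lp <- signal::cheby2(spec$order, spec$stopband_atten_db, ws_low,
                       type = "low")
  filtfilt_padded(lp, filtfilt_padded(hp, x, fs = fs), fs = fs)
}

# filtfilt with odd (point-reflected) extension; pad length capped at 6 s
filtfilt_padded <- function(flt, x, fs = NULL) {
  n <- length(x)
  np <- min(n - 1L, if (is.null(fs)) 500L else as.integer(6 * fs))
  if (np < 1L) return(as.numeric(signal::filtfilt(flt, x)))
  head_pad <- 2 * x[1] - rev(x[2:(np + 1)])
  tail_pad <- 2 * x[n] - rev(x[(n - np):(n - 1)])
  y <- signal::filtfilt(flt, c(head_pad, x, tail_pad))
  y[(np + 1):(np + n)]
}

#' Detect R peaks with the Pan-Tompkins method
#'
#' Classic QRS detection: band-pass 5-15 Hz, five-point derivative,
#' squaring, 150-ms moving-window integration, adaptive signal/noise
#' thresholds with a 200-ms refractory period and a search-back pass, then
#' peak refinement to the local ECG maximum.
#'
#' @param ecg Filtered ECG, mV.
#' @param fs Sampling rate, Hz.
#' @return Integer vector of 1-based R-peak sample indices (ascending;
#'   empty when no QRS-like activity is found).
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (length(ecg) < 2 * fs) {
    stop("ECG must be at least 2 s long for QRS detection", call. = FALSE)
  }
  if (all(abs(ecg - ecg[1]) < .Machine$double.eps * 10)) return(integer(0))

  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  f <- filtfilt_padded(bp, ecg, fs = fs)
  # five-point derivative (Pan-Tompkins kernel), then square
  d <- stats::filter(f, c(1, 2, 0, -2, -1) * fs / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  refrac <- round(0.200 * fs)
  cand <- local_maxima(mwi, min_dist = refrac)
  if (length(cand) == 0) return(integer(0))

  # adaptive thresholding over integrated waveform
  spki <- max(mwi[seq_len(min(length(mwi), 2 * fs))]) / 3
  npki <- mean(mwi[seq_len(min(length(mwi), 2 * fs))]) / 2
  thr <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  for (i in cand) {
    if (mwi[i] > thr) {
      if (length(peaks) == 0 || i - peaks[length(peaks)] >= refrac) {
        peaks <- c(peaks, i)
        spki <- 0.125 * mwi[i] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(peaks) == 0) return(integer(0))

  # search-back: re-scan long RR gaps at half threshold
  if (length(peaks) >= 2) {
    rr_mean <- mean(diff(peaks))
    gaps <- which(diff(peaks) > 1.66 * rr_mean)
    for (g in gaps) {
      lo <- peaks[g] + refrac
      hi <- peaks[g + 1] - refrac
      if (hi <= lo) next
      seg <- cand[cand >= lo & cand <= hi]
      seg <- seg[mwi[seg] > thr / 2]
      peaks <- sort(c(peaks, seg))
    }
  }

  refine_peaks(ecg, peaks, half_window = round(0.100 * fs))
}

#' Detect PPG systolic peaks with two event-related moving averages
#'
#' Block method: the clipped, squared PPG is smoothed with a short
#' (peak-width, 111 ms) and a long (beat-width, 667 ms) moving average;
#' stretches where the short average exceeds the long average plus an
#' offset form blocks of interest, and each sufficiently wide block yields
#' one systolic peak (the PPG maximum inside it).
#'
#' @param ppg Filtered PPG.
#' @param fs Sampling rate, Hz.
#' @param w1_s,w2_s Short/long moving-average widths, seconds.
#' @param beta Offset factor applied to the mean squared signal.
#' @return Integer vector of 1-based systolic-peak indices (ascending).
#' @export
detect_systolic_peaks <- function(ppg, fs, w1_s = 0.111, w2_s = 0.667,
                                  beta = 0.02) {
  if (length(ppg) < 2 * fs) {
    stop("PPG must be at least 2 s long for systolic-peak detection",
         call. = FALSE)
  }
  if (all(abs(ppg - ppg[1]) < .Machine$double.eps * 10)) return(integer(0))

  x <- ppg - mean(ppg)
  x[x < 0] <- 0                        # clip: keep systolic upstrokes
  sq <- x^2
  # centered moving average with partial windows at the edges, so the
  # beat-level threshold is not diluted near the record boundaries
  ma <- function(v, w) {
    w <- max(1L, round(w))
    if (w %% 2 == 0) w <- w + 1L
    half <- (w - 1L) %/% 2L
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  ma_peak <- ma(sq, w1_s * fs)
  ma_beat <- ma(sq, w2_s * fs)
  alpha <- beta * mean(sq)
  interest <- ma_peak > (ma_beat + alpha)

  # contiguous blocks of interest, minimum width w1
  r <- rle(interest)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= round(w1_s * fs)
  purrr::map2_int(starts[keep], ends[keep], function(s, e) {
    as.integer(s + which.max(ppg[s:e]) - 1L)
  }) |> sort()
}

# local maxima with a minimum separation, greedy from the largest
local_maxima <- function(x, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  is_pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(is_pk) == 0) return(integer(0))
  ord <- is_pk[order(x[is_pk], decreasing = TRUE)]
  taken <- logical(n)
  out <- integer(0)
  for (i in ord) {
    lo <- max(1L, i - min_dist)
    hi <- min(n, i + min_dist)
    if (!any(taken[lo:hi])) {
      taken[i] <- TRUE
      out <- c(out, i)
    }
  }
  sort(out)
}

# move each detected index to the signal maximum within +-half_window
refine_peaks <- function(x, idx, half_window) {
  out <- vapply(idx, function(i) {
    lo <- max(1L, i - half_window)
    hi <- min(length(x), i + half_window)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  sort(unique(out))
}

#' Min-max scale a PPG to [0, 1]
#'
#' @param ppg Non-constant numeric vector.
#' @return `(x - min) / (max - min)`.
#' @export
normalize_ppg <- function(ppg) {
  rng <- range(ppg)
  if (rng[1] == rng[2]) {
    stop("cannot normalize a constant PPG (zero range)", call. = FALSE)
  }
  (ppg - rng[1]) / (rng[2] - rng[1])
}

#' Pair each R peak with its corresponding systolic peak
#'
#' For R peak k the corresponding systolic peak is the first systolic peak
#' at or after R peak k and before R peak k+1 (the lower bound is inclusive
#' so that a zero pulse arrival time, where the peaks coincide, still pairs
#' the beats).
#'
#' @param r_peaks,systolic_peaks Ascending 1-based indices.
#' @return Tibble with columns `beat`, `r_idx`, `sys_idx` (only beats with
#'   a correspondence).
#' @export
beat_correspondence <- function(r_peaks, systolic_peaks) {
  if (length(r_peaks) < 2) {
    return(tibble::tibble(beat = integer(), r_idx = integer(),
                          sys_idx = integer()))
  }
  purrr::map_dfr(seq_len(length(r_peaks) - 1L), function(k) {
    s <- systolic_peaks[systolic_peaks >= r_peaks[k] &
                          systolic_peaks < r_peaks[k + 1L]]
    if (length(s) == 0) return(NULL)
    tibble::tibble(beat = k, r_idx = as.integer(r_peaks[k]),
                   sys_idx = as.integer(s[1]))
  })
}

#' Remove the pulse arrival time (Alignment I)
#'
#' Shifts the PPG earlier by the lag between the anchor beat's systolic
#' peak and its R peak (the third systolic peak with a valid R-peak
#' correspondence, skipping forward if beat 3 has none), truncates both
#' channels to common support, and min-max normalizes the PPG. The ECG
#' keeps its mV scale.
#'
#' @param ecg,ppg Filtered channels of equal length.
#' @param fs Sampling rate, Hz.
#' @param annotations List with `r_peaks` and `systolic_peaks` (1-based
#'   ascending indices), e.g. from the detectors or generator truth.
#' @param anchor_beat Which correspondence anchors the lag (default 3).
#' @param record_id Identifier carried through.
#' @param normalize Scale PPG to [0,1] over the full aligned record
#'   (default) or leave unscaled (`FALSE`) for leakage-free experiments
#'   that normalize on the training minute only.
#' @return An object of class `aligned_pair`: list with `ecg`, `ppg`, `fs`,
#'   `applied_lag` (samples the PPG was advanced), `record_id`.
#' @export
align_pair <- function(ecg, ppg, fs, annotations, anchor_beat = 3,
                       record_id = "record", normalize = TRUE) {
  stopifnot(length(ecg) == length(ppg))
  corr <- beat_correspondence(annotations$r_peaks,
                              annotations$systolic_peaks)
  if (nrow(corr) < 3) {
    stop("alignment error: need >= 3 beat correspondences, found ",
         nrow(corr), call. = FALSE)
  }
  anchor_pos <- which(corr$beat >= anchor_beat)
  if (length(anchor_pos) == 0) {
    warning("no correspondence at or after anchor beat ", anchor_beat,
            "; using the last available beat")
    anchor_pos <- nrow(corr)
  } else {
    if (corr$beat[anchor_pos[1]] != anchor_beat) {
      warning("anchor beat ", anchor_beat, " has no systolic ",
              "correspondence; using beat ", corr$beat[anchor_pos[1]])
    }
    anchor_pos <- anchor_pos[1]
  }
  lag <- corr$sys_idx[anchor_pos] - corr$r_idx[anchor_pos]
  if (lag < 0) {
    stop("alignment error: negative pulse arrival time (lag = ", lag,
         " samples); PPG should lag the ECG", call. = FALSE)
  }
  n <- length(ecg)
  ppg_shifted <- ppg[(1 + lag):n]       # advance PPG by `lag`
  ecg_trunc <- ecg[1:(n - lag)]
  if (normalize) ppg_shifted <- normalize_ppg(ppg_shifted)
  structure(
    list(ecg = ecg_trunc, ppg = ppg_shifted, fs = fs,
         applied_lag = as.integer(lag), record_id = record_id),
    class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf(
    "<aligned_pair> %s: %d samples @ %g Hz, PPG advanced by %d samples\n",
    x$record_id, length(x$ecg), x$fs, x$applied_lag))
  invisible(x)
}

#' @export
as_tibble.aligned_pair <- function(x, ...) {
  tibble::tibble(time = (seq_along(x$ecg) - 1) / x$fs,
                 ecg = x$ecg, ppg = x$ppg)
}

#' Filter, detect peaks, and align one record
#'
#' Convenience wrapper running the full preprocessing chain: band-pass both
#' channels, detect R and systolic peaks, and remove the pulse arrival
#' time.
#'
#' @param record An [ecg_record()].
#' @param ecg_spec,ppg_spec [filter_spec()]s for the two channels.
#' @param anchor_beat Anchor beat for Alignment I (default 3).
#' @return An `aligned_pair` (see [align_pair()]).
#' @export
preprocess_record <- function(record, ecg_spec = ecg_filter_spec(),
                              ppg_spec = ppg_filter_spec(),
                              anchor_beat = 3) {
  stopifnot(inherits(record, "ecg_record"))
  ecg_f <- bandpass(record$ecg, record$fs, ecg_spec)
  ppg_f <- bandpass(record$ppg, record$fs, ppg_spec)
  ann <- list(r_peaks = detect_r_peaks(ecg_f, record$fs),
              systolic_peaks = detect_systolic_peaks(ppg_f, record$fs))
  align_pair(ecg_f, ppg_f, record$fs, ann, anchor_beat = anchor_beat,
             record_id = record$record_id)
}
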