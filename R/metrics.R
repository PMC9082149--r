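#' Pearson correlation between reference and reconstructed ECG
#'
#' Direct evaluation of the product-moment formula: the ratio of the
#' centered cross-product to the product of the centered sum-of-squares
#' roots.
#'
#' @param ref,rec Equal-length numeric vectors (length >= 2), both
#'   non-constant.
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(ref, rec) {
  check_equal_length(ref, rec)
  if (length(ref) < 2) stop("need at least 2 samples", call. = FALSE)
  dr <- ref - mean(ref)
  dc <- rec - mean(rec)
  den <- sqrt(sum(dr^2)) * sqrt(sum(dc^2))
  if (den == 0) {
    stop("Pearson r undefined for a constant input", call. = FALSE)
  }
  max(-1, min(1, sum(dr * dc) / den))
}

#' Root mean square error
#'
#' @param ref,rec Equal-length numeric vectors.
#' @return `sqrt(mean((ref - rec)^2))`, in the signals' amplitude units
#'   (mV for ECG).
#' @export
rmse <- function(ref, rec) {
  check_equal_length(ref, rec)
  sqrt(mean((ref - rec)^2))
}

check_equal_length <- function(ref, rec) {
  if (length(ref) != length(rec)) {
    stop("sequences have unequal lengths: ", length(ref), " vs ",
         length(rec), call. = FALSE)
  }
  if (length(ref) == 0) stop("empty input", call. = FALSE)
  invisible(TRUE)
}

#' Dynamic time warping distance and warping path
#'
#' Builds the m x m local-cost matrix with
#' `d_ij = sqrt((i - j)^2 + (ref_i - rec_j)^2)` — the index difference in
#' raw sample units and the amplitude difference in signal units — and
#' finds the monotone path from (1,1) to (m,m) (steps (1,0), (0,1), (1,1))
#' minimizing the summed cost. The distance carries the ECG's mV label by
#' convention even though the cost mixes units; `index_cost = FALSE` gives
#' the unit-consistent amplitude-only cost.
#'
#' @param ref,rec Equal-length numeric vectors.
#' @param band_radius Sakoe-Chiba band half-width in samples, or `NULL`
#'   (default) for the full matrix. A radius of one second of samples is
#'   ample for stitched multi-minute signals, whose optimal path hugs the
#'   diagonal.
#' @param index_cost Include the `(i - j)^2` term (default TRUE).
#' @param return_path Return the warping path (default TRUE).
#' @return List of class `dtw_result`: `distance` (mV), and with
#'   `return_path` a tibble `path` with columns `i`, `j` (1-based, anchored
#'   at (1,1) and (m,m)).
#' @export
dtw <- function(ref, rec, band_radius = NULL, index_cost = TRUE,
                return_path = TRUE) {
  check_equal_length(ref, rec)
  radius <- if (is.null(band_radius)) -1L else as.integer(band_radius)
  out <- dtw_cpp(as.numeric(ref), as.numeric(rec), radius,
                 isTRUE(index_cost), isTRUE(return_path))
  res <- list(distance = out$distance)
  if (return_path) {
    res$path <- tibble::tibble(i = out$path_i, j = out$path_j)
  }
  structure(res, class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance = %.6g", x$distance))
  if (!is.null(x$path)) cat(sprintf(" (path length %d)", nrow(x$path)))
  cat("\n")
  invisible(x)
}

#' Plot a warping path
#'
#' @param object A `dtw_result` with a path.
#' @param ... Unused.
#' @return A ggplot of the path in the (i, j) plane with the diagonal for
#'   reference.
#' @export
autoplot.dtw_result <- function(object, ...) {
  if (is.null(object$path)) stop("no path stored; rerun with return_path = TRUE",
                                 call. = FALSE)
  ggplot2::ggplot(object$path, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "reference index", y = "reconstruction index",
                  title = sprintf("DTW distance %.3f mV", object$distance))
}

#' Normalize a DTW distance by signal duration
#'
#' @param distance DTW distance (mV).
#' @param duration_s Signal length in seconds (> 0).
#' @return Distance per second, mV/s.
#' @export
dtw_per_second <- function(distance, duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  distance / duration_s
}

#' Cross-correlation lag alignment (Alignment II)
#'
#' Searches integer lags within `window_ms` for the one maximizing the
#' normalized cross-correlation of the overlapping samples, then shifts the
#' reconstruction by that lag. Positive lag means the reconstruction lags
#' the reference and is advanced. Ties go to the smallest |lag|, negative
#' before positive. Both series are truncated to the overlap (no padding).
#'
#' @param ref,rec Equal-length numeric vectors.
#' @param fs Sampling rate, Hz.
#' @param window_ms Maximum lag magnitude, milliseconds (default 80).
#' @return List with `lag` (samples), `ref` and `rec` (the aligned,
#'   truncated overlap), `correlation` (at the chosen lag).
#' @export
xcorr_align <- function(ref, rec, fs, window_ms = 80) {
  check_equal_length(ref, rec)
  if (window_ms < 0) stop("window_ms must be >= 0", call. = FALSE)
  max_lag <- round(window_ms * fs / 1000)
  n <- length(ref)
  if (max_lag >= n) {
    stop("alignment window (", max_lag, " samples) must be smaller than ",
         "the signal (", n, " samples)", call. = FALSE)
  }
  lags <- seq.int(-max_lag, max_lag)
  # order: |lag| ascending, negative first on ties
  lags <- lags[order(abs(lags), lags)]
  best <- list(lag = 0L, corr = -Inf)
  for (k in lags) {
    ov <- overlap_at_lag(ref, rec, k)
    if (stats::sd(ov$ref) == 0 || stats::sd(ov$rec) == 0) next
    r <- pearson_r(ov$ref, ov$rec)
    if (r > best$corr + 1e-15) best <- list(lag = k, corr = r)
  }
  ov <- overlap_at_lag(ref, rec, best$lag)
  list(lag = as.integer(best$lag), ref = ov$ref, rec = ov$rec,
       correlation = best$corr)
}

# positive lag k: rec lags ref, so advance rec by k samples
overlap_at_lag <- function(ref, rec, k) {
  n <- length(ref)
  if (k >= 0) {
    list(ref = ref[1:(n - k)], rec = rec[(1 + k):n])
  } else {
    list(ref = ref[(1 - k):n], rec = rec[1:(n + k)])
  }
}

#' Evaluate reconstructed ECG segments against the reference
#'
#' Computes, per segment: Pearson r, rmse (mV), DTW distance d (mV) and its
#' per-second value, and the cross-correlation-aligned variants r_a,
#' rmse_a, d_a (per-segment lags). The stitched concatenations yield r_s,
#' rmse_s, d_s, per-second d_bar_s, and aligned r_sa, rmse_sa (one global
#' lag).
#'
#' @param ref_segments,rec_segments Matrices with one window per row
#'   (reference and reconstructed ECG), matched in order.
#' @param fs Sampling rate, Hz.
#' @param segment_s Window length in seconds.
#' @param align_window_ms Alignment II search window (default 80 ms).
#' @param stitched_band_radius Sakoe-Chiba half-width for the stitched DTW,
#'   samples; defaults to one second (`fs`). `NULL` computes the full
#'   matrix.
#' @return An object of class `ecg_eval`: list with `segments` (tibble, one
#'   row per segment), `stitched` (named list), `fs`, `segment_s`.
#' @export
evaluate_reconstruction <- function(ref_segments, rec_segments, fs,
                                    segment_s,
                                    align_window_ms = 80,
                                    stitched_band_radius = fs) {
  ref_segments <- as.matrix(ref_segments)
  rec_segments <- as.matrix(rec_segments)
  if (nrow(ref_segments) != nrow(rec_segments) ||
      ncol(ref_segments) != ncol(rec_segments)) {
    stop("reference and reconstruction segment sets differ in shape",
         call. = FALSE)
  }
  if (nrow(ref_segments) == 0) stop("no segments to evaluate", call. = FALSE)

  per_seg <- purrr::map_dfr(seq_len(nrow(ref_segments)), function(s) {
    ref <- ref_segments[s, ]
    rec <- rec_segments[s, ]
    al <- xcorr_align(ref, rec, fs, align_window_ms)
    d <- dtw(ref, rec, return_path = FALSE)$distance
    d_a <- dtw(al$ref, al$rec, return_path = FALSE)$distance
    tibble::tibble(
      segment = s,
      r = pearson_r(ref, rec),
      rmse = rmse(ref, rec),
      d = d,
      d_bar = dtw_per_second(d, segment_s),
      lag = al$lag,
      r_a = pearson_r(al$ref, al$rec),
      rmse_a = rmse(al$ref, al$rec),
      d_a = d_a)
  })

  ref_all <- stitch(ref_segments)
  rec_all <- stitch(rec_segments)
  dur <- length(ref_all) / fs
  al <- xcorr_align(ref_all, rec_all, fs, align_window_ms)
  d_s <- dtw(ref_all, rec_all, band_radius = stitched_band_radius,
             return_path = FALSE)$distance
  stitched <- list(
    r_s = pearson_r(ref_all, rec_all),
    rmse_s = rmse(ref_all, rec_all),
    d_s = d_s,
    d_bar_s = dtw_per_second(d_s, dur),
    lag_s = al$lag,
    r_sa = pearson_r(al$ref, al$rec),
    rmse_sa = rmse(al$ref, al$rec),
    duration_s = dur)

  structure(list(segments = per_seg, stitched = stitched, fs = fs,
                 segment_s = segment_s),
            class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ecg_eval> %d x %d-s segments: r = %.3f +- %.3f, rmse = %.3f +- %.3f mV\n",
    nrow(x$segments), x$segment_s, g$r_mean, g$r_sd, g$rmse_mean, g$rmse_sd))
  cat(sprintf(
    "  stitched (%.0f s): r_s = %.3f, r_sa = %.3f, rmse_s = %.3f mV, d_bar_s = %.3f mV/s\n",
    x$stitched$duration_s, x$stitched$r_s, x$stitched$r_sa,
    x$stitched$rmse_s, x$stitched$d_bar_s))
  invisible(x)
}

#' Per-segment metrics of an evaluation
#'
#' @param x An `ecg_eval`.
#' @param ... Unused.
#' @return Tibble, one row per segment, columns `segment, r, rmse, d,
#'   d_bar, lag, r_a, rmse_a, d_a`.
#' @export
tidy.ecg_eval <- function(x, ...) x$segments

#' One-row summary of an evaluation
#'
#' Mean and standard deviation of each per-segment metric plus the stitched
#' metrics, mirroring a per-record row of the reference results table.
#'
#' @param x An `ecg_eval`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.ecg_eval <- function(x, ...) {
  s <- x$segments
  msd <- function(v) list(mean = mean(v), sd = stats::sd(v))
  cols <- c("r", "rmse", "d", "d_bar", "r_a", "rmse_a", "d_a")
  out <- purrr::map(cols, function(cn) {
    m <- msd(s[[cn]])
    rlang::set_names(list(m$mean, m$sd),
                     paste0(cn, c("_mean", "_sd")))
  }) |> purrr::flatten()
  tibble::as_tibble(c(
    list(n_segments = nrow(s), segment_s = x$segment_s),
    out, x$stitched))
}

#' Pool evaluations across records
#'
#' Per-segment columns are pooled over all segments of all records;
#' stitched columns are aggregated across records (mean +- sd), matching a
#' cohort summary row.
#'
#' @param evals List of `ecg_eval` objects.
#' @return One-row tibble of pooled means and standard deviations.
#' @export
pool_evals <- function(evals) {
  stopifnot(length(evals) >= 1,
            all(purrr::map_lgl(evals, inherits, "ecg_eval")))
  seg <- purrr::map_dfr(evals, "segments")
  sti <- purrr::map_dfr(evals, ~tibble::as_tibble(.x$stitched))
  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  out <- list(n_records = length(evals), n_segments = nrow(seg))
  for (cn in c("r", "rmse", "d", "d_bar", "r_a", "rmse_a", "d_a")) {
    m <- msd(seg[[cn]])
    out[[paste0(cn, "_mean")]] <- m[["mean"]]
    out[[paste0(cn, "_sd")]] <- m[["sd"]]
  }
  for (cn in c("r_s", "rmse_s", "d_s", "d_bar_s", "r_sa", "rmse_sa")) {
    m <- msd(sti[[cn]])
    out[[paste0(cn, "_mean")]] <- m[["mean"]]
    out[[paste0(cn, "_sd")]] <- m[["sd"]]
  }
  tibble::as_tibble(out)
}

#' Plot per-segment metrics of an evaluation
#'
#' @param object An `ecg_eval`.
#' @param ... Unused.
#' @return A ggplot of r / r_a and rmse / rmse_a per segment.
#' @export
autoplot.ecg_eval <- function(object, ...) {
  df <- object$segments |>
    dplyr::select("segment", "r", "r_a", "rmse", "rmse_a") |>
    tidyr::pivot_longer(-"segment", names_to = "metric")
  df$family <- ifelse(grepl("^r", df$metric) & !grepl("rmse", df$metric),
                      "Pearson r", "rmse (mV)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~family, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "segment", y = NULL, colour = NULL)
}
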