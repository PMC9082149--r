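#' Train/validation/gap/test split specification
#'
#' The default layout takes the first 48 s of the aligned record for
#' training, the next 12 s for validation, discards 12 s, and tests on the
#' following 228 s (a test:train duration ratio of 4.75). Each role is cut
#' into contiguous non-overlapping `segment_s`-second windows.
#'
#' @param train_s,val_s,gap_s,test_s Durations in seconds.
#' @param segment_s Segment length in seconds (1-4 in the reference design;
#'   any positive integer dividing `test_s` is accepted).
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(train_s = 48, val_s = 12, gap_s = 12, test_s = 228,
                       segment_s = 1) {
  stopifnot(train_s >= 0, val_s >= 0, gap_s >= 0, test_s > 0,
            segment_s > 0, segment_s == round(segment_s))
  if (test_s %% segment_s != 0) {
    stop("test_s (", test_s, ") must be divisible by segment_s (",
         segment_s, ")", call. = FALSE)
  }
  structure(list(train_s = train_s, val_s = val_s, gap_s = gap_s,
                 test_s = test_s, segment_s = as.integer(segment_s)),
            class = "split_spec")
}

#' Segment counts implied by a split
#'
#' @param spec A [split_spec()].
#' @return A tibble with one row per role and columns `role`, `seconds`,
#'   `n_segments`.
#' @examples
#' segment_counts(split_spec(segment_s = 4))
#' @export
segment_counts <- function(spec) {
  tibble::tibble(
    role = c("train", "validation", "test"),
    seconds = c(spec$train_s, spec$val_s, spec$test_s),
    n_segments = floor(c(spec$train_s, spec$val_s, spec$test_s) /
                         spec$segment_s))
}

#' Split an aligned pair into segmented train/validation/test sets
#'
#' Intervals are contiguous and in order train, validation, gap
#' (discarded), test; each interval is cut into non-overlapping windows of
#' `segment_s` seconds whose in-order concatenation reproduces the interval
#' exactly.
#'
#' @param pair An `aligned_pair` from [align_pair()].
#' @param spec A [split_spec()].
#' @return A list of class `dataset_split` with elements `train`,
#'   `validation`, `test` — each a `segment_set`: list with matrices `ecg`
#'   and `ppg` (one row per segment), `role`, `segment_s`, `fs` — plus
#'   `spec`.
#' @export
split_pair <- function(pair, spec = split_spec()) {
  stopifnot(inherits(pair, "aligned_pair"), inherits(spec, "split_spec"))
  fs <- pair$fs
  need_s <- spec$train_s + spec$val_s + spec$gap_s + spec$test_s
  have_s <- length(pair$ecg) / fs
  if (have_s < need_s) {
    stop(sprintf(
      "record too short: %.1f s available, %.1f s required (%g train + %g val + %g gap + %g test)",
      have_s, need_s, spec$train_s, spec$val_s, spec$gap_s, spec$test_s),
      call. = FALSE)
  }
  offs <- round(cumsum(c(0, spec$train_s, spec$val_s, spec$gap_s)) * fs)
  take <- function(start, dur_s, role) {
    idx <- (start + 1):(start + round(dur_s * fs))
    new_segment_set(pair$ecg[idx], pair$ppg[idx], role, spec$segment_s, fs)
  }
  structure(
    list(train = take(offs[1], spec$train_s, "train"),
         validation = take(offs[2], spec$val_s, "validation"),
         test = take(offs[4], spec$test_s, "test"),
         spec = spec),
    class = "dataset_split")
}

new_segment_set <- function(ecg, ppg, role, segment_s, fs) {
  len <- segment_s * fs
  n_seg <- floor(length(ecg) / len)
  used <- seq_len(n_seg * len)
  structure(
    list(ecg = matrix(ecg[used], nrow = n_seg, ncol = len, byrow = TRUE),
         ppg = matrix(ppg[used], nrow = n_seg, ncol = len, byrow = TRUE),
         role = role, segment_s = segment_s, fs = fs),
    class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %s: %d segments x %d s (%d samples each)\n",
              x$role, nrow(x$ecg), x$segment_s, ncol(x$ecg)))
  invisible(x)
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>\n")
  for (r in c("train", "validation", "test")) print(x[[r]])
  invisible(x)
}

#' @export
as_tibble.dataset_split <- function(x, ...) {
  purrr::map_dfr(c("train", "validation", "test"), function(r) {
    tibble::tibble(role = r, n_segments = nrow(x[[r]]$ecg),
                   segment_s = x[[r]]$segment_s,
                   seconds = nrow(x[[r]]$ecg) * x[[r]]$segment_s)
  })
}

#' Fit a split to the usable duration of an aligned record
#'
#' Alignment I truncates the record, so the nominal layout may no longer
#' fit. The discarded gap absorbs the truncation first (down to 0 s); if
#' the record is still too short, `test_s` drops to the largest fitting
#' multiple of 12 s (keeping it divisible by every segment length 1-4),
#' with train and validation durations fixed.
#'
#' @param pair An `aligned_pair`.
#' @param spec Nominal [split_spec()].
#' @return A [split_spec()] that fits `pair`.
#' @export
fit_split_spec <- function(pair, spec = split_spec()) {
  stopifnot(inherits(pair, "aligned_pair"), inherits(spec, "split_spec"))
  have_s <- length(pair$ecg) / pair$fs
  fixed <- spec$train_s + spec$val_s
  slack <- have_s - fixed - spec$test_s
  if (slack >= spec$gap_s) return(spec)
  if (slack >= 0) {
    return(split_spec(spec$train_s, spec$val_s, slack, spec$test_s,
                      spec$segment_s))
  }
  step <- lcm_int(12L, spec$segment_s)
  test_s <- floor((have_s - fixed) / step) * step
  if (test_s <= 0) {
    stop(sprintf(
      "record too short: %.1f s available, need > %g s for train/val plus one %d-s test block",
      have_s, fixed, step), call. = FALSE)
  }
  split_spec(spec$train_s, spec$val_s, 0, test_s, spec$segment_s)
}

lcm_int <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  as.integer(a / gcd(a, b) * b)
}

#' Stitch reconstructed segments back into one signal
#'
#' Plain in-order concatenation: segments are placed adjacent to each other
#' with no overlap and no cross-fade, so stitching the segmentation of a
#' contiguous interval reproduces that interval exactly.
#'
#' @param segments A matrix (one row per segment) or a list of equal-length
#'   numeric vectors, in order.
#' @return Numeric vector of length `sum of segment lengths`.
#' @export
stitch <- function(segments) {
  if (is.matrix(segments)) {
    if (nrow(segments) == 0) stop("no segments to stitch", call. = FALSE)
    return(as.numeric(t(segments)))
  }
  if (!is.list(segments) || length(segments) == 0) {
    stop("no segments to stitch", call. = FALSE)
  }
  lens <- lengths(segments)
  if (length(unique(lens)) != 1) {
    stop("segments have unequal lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  unlist(segments, use.names = FALSE)
}
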