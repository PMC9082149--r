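#' Paired ECG/PPG record
#'
#' Container for a simultaneously recorded single-lead ECG (mV) and PPG
#' (arbitrary units) sampled at a common rate. Channels must have equal
#' length and contain only finite values.
#'
#' @param ecg Numeric vector, ECG amplitudes in mV.
#' @param ppg Numeric vector, PPG amplitudes in arbitrary units.
#' @param fs Sampling rate in Hz (> 0).
#' @param record_id Character scalar identifying the record.
#' @param disease_flag Optional logical metadata flag.
#'
#' @return An object of class `ecg_record`: a list with elements
#'   `record_id`, `fs`, `ecg`, `ppg`, `disease_flag`.
#' @examples
#' r <- ecg_record(sin(1:250 / 10), cos(1:250 / 10), fs = 125)
#' as_tibble(r)
#' @export
ecg_record <- function(ecg, ppg, fs, record_id = "record", disease_flag = NA) {
  ecg <- as.numeric(ecg)
  ppg <- as.numeric(ppg)
  if (length(ecg) < 1L || length(ecg) != length(ppg)) {
    stop("`ecg` and `ppg` must have equal length >= 1 (got ",
         length(ecg), " and ", length(ppg), ")", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(ecg)) || !all(is.finite(ppg))) {
    stop("all ECG and PPG samples must be finite", call. = FALSE)
  }
  structure(
    list(record_id = as.character(record_id), fs = as.numeric(fs),
         ecg = ecg, ppg = ppg, disease_flag = disease_flag),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$ecg), x$fs, length(x$ecg) / x$fs))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
as_tibble.ecg_record <- function(x, ...) {
  tibble::tibble(
    time = (seq_along(x$ecg) - 1) / x$fs,
    ecg = x$ecg,
    ppg = x$ppg
  )
}

#' Read a paired ECG/PPG record
#'
#' Reads a record from the package's canonical CSV interchange format
#' (header exactly `time,ecg,ppg`, time in seconds starting at 0 with a
#' constant step) or from a WFDB-style header/data pair.
#'
#' @param path Path to a `.csv` file or a WFDB `.hea` header.
#' @param format `"csv"` (default) or `"wfdb"`.
#' @param record_id Identifier to attach; defaults to the file stem.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"),
                        record_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "wfdb") return(read_record_wfdb(path, record_id))
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time", "ecg", "ppg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("CSV format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  }
  if (nrow(df) < 2) stop("CSV format error: need >= 2 rows", call. = FALSE)
  dt <- diff(df$time)
  step <- stats::median(dt)
  if (step <= 0 || any(abs(dt - step) > 1e-6 * max(step, 1))) {
    stop("CSV format error: non-uniform time step in ", path, call. = FALSE)
  }
  fs <- 1 / step
  # snap to an integer rate when the time column's decimal rounding is the
  # only reason it is not one (e.g. 0.008 s -> 124.99999997 Hz)
  if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  ecg_record(df$ecg, df$ppg, fs = fs, record_id = record_id)
}

# Minimal WFDB adapter: plain-text header naming a CSV-like data file with
# one column per channel (no binary formats). Header line 1:
# "<name> <n_sig> <fs> <n_samp>"; subsequent lines: "<file> <desc>".
read_record_wfdb <- function(path, record_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 3) stop("WFDB format error: bad header line", call. = FALSE)
  fs <- as.numeric(hdr[3])
  sig_lines <- lines[-1]
  if (length(sig_lines) < 2) {
    stop("WFDB format error: need two signal lines (ECG and PPG)", call. = FALSE)
  }
  datafile <- strsplit(trimws(sig_lines[1]), "\\s+")[[1]][1]
  dat <- utils::read.csv(file.path(dirname(path), datafile),
                         check.names = FALSE)
  need <- c("ecg", "ppg")
  if (!all(need %in% names(dat))) {
    stop("WFDB format error: data file must have columns ecg, ppg",
         call. = FALSE)
  }
  ecg_record(dat$ecg, dat$ppg, fs = fs, record_id = record_id)
}

#' Write a record to the canonical CSV format
#'
#' Writes `time,ecg,ppg` with time starting at 0 in steps of `1/fs`, at
#' full precision so that [read_record()] round-trips bit-stably.
#'
#' @param record An [ecg_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  if (!all(is.finite(record$ecg)) || !all(is.finite(record$ppg))) {
    stop("record contains non-finite samples; refusing to write",
         call. = FALSE)
  }
  df <- as_tibble(record)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open ", path, " for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines("time,ecg,ppg", con)
  body <- paste(format(df$time, digits = 17, trim = TRUE, scientific = FALSE),
                format(df$ecg, digits = 17, trim = TRUE),
                format(df$ppg, digits = 17, trim = TRUE), sep = ",")
  writeLines(body, con)
  invisible(path)
}

#' Plot a record's channels
#'
#' @param object An [ecg_record()].
#' @param ... Unused.
#' @return A ggplot with ECG and PPG facets over time.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ecg_record <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("ecg", "ppg"), names_to = "channel",
                        values_to = "amplitude")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = object$record_id)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
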