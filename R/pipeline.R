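#' Default run configuration
#'
#' One declarative list covering every stage: filtering, Alignment I,
#' splitting/segmentation, the BiLSTM, evaluation, and the synthetic
#' generator. Unknown keys are rejected by [validate_run_config()].
#'
#' @return Nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    filter = list(ecg = list(band = c(0.5, 20)),
                  ppg = list(band = c(0.5, 10)),
                  order = 4L, stopband_atten_db = 40),
    align = list(anchor_beat = 3L, rpeak_tolerance_ms = 40),
    split = list(train_s = 48, val_s = 12, gap_s = 12, test_s = 228,
                 segment_s = 1L),
    model = list(hidden_units = 25L, l1 = 1e-4, l2 = 1e-4,
                 learning_rate = 0.001, batch_size = 1L,
                 max_epochs = 1000L, early_stop_patience = 50L),
    eval = list(align_window_ms = 80),
    simulate = list(fs = 125, duration_s = 300, heart_rate_bpm = 60,
                    rr_jitter_sd_s = 0.02, pat_s = 0.2, noise_sd = 0))
}

#' Read and validate a run configuration
#'
#' Reads YAML, merges over [default_run_config()], and rejects unknown
#' keys so that typos fail before any compute.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list merged last (e.g. from CLI flags).
#' @return Validated config list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- merge_config(cfg, user, path = "")
  cfg <- merge_config(cfg, overrides, path = "")
  validate_run_config(cfg)
  cfg
}

merge_config <- function(base, user, path) {
  if (length(user) == 0) return(base)
  for (k in names(user)) {
    here <- paste0(path, if (nzchar(path)) "." else "", k)
    if (!k %in% names(base)) {
      stop("unknown config key: ", here, call. = FALSE)
    }
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], here)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' @rdname read_run_config
#' @param cfg Config list to validate.
#' @export
validate_run_config <- function(cfg) {
  with(cfg$split, {
    if (test_s %% segment_s != 0) {
      stop("config error: split.test_s (", test_s,
           ") not divisible by split.segment_s (", segment_s, ")",
           call. = FALSE)
    }
  })
  stopifnot(cfg$filter$ecg$band[1] > 0,
            cfg$filter$ecg$band[2] > cfg$filter$ecg$band[1],
            cfg$model$hidden_units >= 1, cfg$model$max_epochs >= 1,
            cfg$eval$align_window_ms >= 0)
  invisible(cfg)
}

#' Run the full reconstruction pipeline on one record
#'
#' preprocess (filter, detect, Alignment I) -> split/segment -> train the
#' subject-specific BiLSTM -> reconstruct the test PPG windows -> stitch ->
#' Alignment II -> evaluate. One record is one subject and one model.
#'
#' @param record An [ecg_record()].
#' @param config A config list from [read_run_config()] /
#'   [default_run_config()].
#' @param out_dir Optional directory: writes the reconstructed test ECG
#'   (CSV), the model (JSON), and the evaluation report (JSON).
#' @param verbose Log per-stage progress to stderr.
#' @return List of class `pipeline_result`: `record_id`, `aligned`
#'   (`aligned_pair`), `split` sizes tibble, `model` (trained
#'   `reconstructor`), `eval` (`ecg_eval`), `log` (tibble of stage
#'   decisions).
#' @export
run_pipeline <- function(record, config = default_run_config(),
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  validate_run_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  logs <- list()
  note <- function(stage, key, value) {
    logs[[length(logs) + 1]] <<- tibble::tibble(
      stage = stage, key = key, value = as.character(value))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] stage %s failed: %s", record$record_id, name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("[%s] preprocess", record$record_id)
  aligned <- stage("preprocess", {
    ecg_spec <- filter_spec(config$filter$ecg$band[1],
                            config$filter$ecg$band[2],
                            config$filter$order,
                            config$filter$stopband_atten_db)
    ppg_spec <- filter_spec(config$filter$ppg$band[1],
                            config$filter$ppg$band[2],
                            config$filter$order,
                            config$filter$stopband_atten_db)
    preprocess_record(record, ecg_spec, ppg_spec,
                      anchor_beat = config$align$anchor_beat)
  })
  note("preprocess", "applied_lag_samples", aligned$applied_lag)

  say("[%s] split/segment", record$record_id)
  sp <- stage("split", {
    nominal <- split_spec(config$split$train_s, config$split$val_s,
                          config$split$gap_s, config$split$test_s,
                          config$split$segment_s)
    fitted <- fit_split_spec(aligned, nominal)
    if (fitted$gap_s != nominal$gap_s) {
      note("split", "gap_s_after_truncation", fitted$gap_s)
    }
    if (fitted$test_s != nominal$test_s) {
      note("split", "test_s_after_truncation", fitted$test_s)
    }
    split_pair(aligned, fitted)
  })
  for (r in c("train", "validation", "test")) {
    note("split", paste0(r, "_segments"), nrow(sp[[r]]$ecg))
  }

  say("[%s] train BiLSTM", record$record_id)
  model <- stage("train", {
    cfg <- reconstructor_config(
      hidden_units = config$model$hidden_units,
      l1 = config$model$l1, l2 = config$model$l2,
      learning_rate = config$model$learning_rate,
      max_epochs = config$model$max_epochs,
      early_stop_patience = config$model$early_stop_patience,
      seed = config$seed)
    m <- build_reconstructor(cfg, ncol(sp$train$ppg))
    train_reconstructor(m, sp$train, sp$validation)
  })
  note("train", "epochs_run", model$epochs_run)
  note("train", "best_epoch", model$best_epoch)

  say("[%s] reconstruct + evaluate", record$record_id)
  rec_windows <- stage("reconstruct", reconstruct(model, sp$test))
  ev <- stage("evaluate", {
    evaluate_reconstruction(sp$test$ecg, rec_windows, aligned$fs,
                            config$split$segment_s,
                            align_window_ms = config$eval$align_window_ms)
  })
  note("evaluate", "stitched_lag_samples", ev$stitched$lag_s)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rec_ecg <- stitch(rec_windows)
    utils::write.csv(
      data.frame(time = (seq_along(rec_ecg) - 1) / aligned$fs,
                 ecg_rec = rec_ecg),
      file.path(out_dir, paste0(record$record_id, "_reconstructed.csv")),
      row.names = FALSE)
    save_reconstructor(model,
                       file.path(out_dir, paste0(record$record_id,
                                                 "_model.json")))
    jsonlite::write_json(
      list(schema = "ecgrecon/report/v1", record_id = record$record_id,
           glance = glance(ev), segments = tidy(ev)),
      file.path(out_dir, paste0(record$record_id, "_report.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  structure(
    list(record_id = record$record_id, aligned = aligned,
         split = as_tibble(sp), model = model, eval = ev,
         log = dplyr::bind_rows(logs)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s\n", x$record_id))
  print(x$eval)
  invisible(x)
}

#' Run the pipeline on a cohort and pool the report
#'
#' @param records List of [ecg_record()]s (one subject-specific model per
#'   record).
#' @param config Shared run configuration; the seed is offset per record so
#'   subjects train independently but reproducibly.
#' @param verbose Log progress.
#' @return List with `per_record` (named list of `pipeline_result`) and
#'   `pooled` (one-row tibble from [pool_evals()]).
#' @export
run_cohort <- function(records, config = default_run_config(),
                       verbose = FALSE) {
  stopifnot(length(records) >= 1)
  results <- purrr::map(seq_along(records), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    run_pipeline(records[[i]], cfg, verbose = verbose)
  })
  names(results) <- names(records) %||%
    purrr::map_chr(results, "record_id")
  list(per_record = results,
       pooled = pool_evals(purrr::map(results, "eval")))
}
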