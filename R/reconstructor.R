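#' BiLSTM reconstructor configuration
#'
#' Hyperparameters of the subject-specific sequence-to-sequence model: one
#' bidirectional LSTM layer (25 hidden units per direction, sequence
#' output, L1 + L2 regularization on the input kernels) followed by a
#' per-timestep linear map to one output value. Trained with Adam at
#' batch size 1 on mean squared error.
#'
#' @param hidden_units LSTM units per direction (default 25).
#' @param l1,l2 Kernel-regularizer weights (default 1e-4 each).
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size Windows per update; only 1 is supported (the reference
#'   training regime).
#' @param max_epochs Upper bound on training epochs (default 1000).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (default 50); the best-validation parameters are restored.
#'   Set to 0 to always run `max_epochs`.
#' @param shuffle Shuffle training windows each epoch (default TRUE).
#' @param seed Integer seed for initialization and shuffling.
#' @return A list of class `reconstructor_config`.
#' @export
reconstructor_config <- function(hidden_units = 25, l1 = 1e-4, l2 = 1e-4,
                                 learning_rate = 0.001, batch_size = 1,
                                 max_epochs = 1000,
                                 early_stop_patience = 50,
                                 shuffle = TRUE, seed = 1L) {
  if (hidden_units < 1 || hidden_units != round(hidden_units)) {
    stop("hidden_units must be a positive integer", call. = FALSE)
  }
  stopifnot(l1 >= 0, l2 >= 0, learning_rate > 0, max_epochs >= 1,
            early_stop_patience >= 0)
  if (batch_size != 1) {
    stop("only batch_size = 1 is supported", call. = FALSE)
  }
  structure(
    list(hidden_units = as.integer(hidden_units), l1 = l1, l2 = l2,
         learning_rate = learning_rate, batch_size = 1L,
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         loss = "mse", shuffle = isTRUE(shuffle), seed = as.integer(seed)),
    class = "reconstructor_config")
}

#' Build an (untrained) BiLSTM reconstructor
#'
#' Parameters are initialized from the config seed (Glorot-uniform kernels,
#' zero biases with the forget-gate bias at 1), so two builds with the same
#' seed are identical.
#'
#' @param config A [reconstructor_config()].
#' @param input_length Samples per window (`fs * segment_s`).
#' @return An object of class `reconstructor`.
#' @export
build_reconstructor <- function(config = reconstructor_config(),
                                input_length) {
  stopifnot(inherits(config, "reconstructor_config"))
  if (input_length < 1 || input_length != round(input_length)) {
    stop("input_length must be a positive integer", call. = FALSE)
  }
  structure(
    list(config = config, input_length = as.integer(input_length),
         params = bilstm_init_params(config$hidden_units, config$seed),
         trained = FALSE, history = NULL),
    class = "reconstructor")
}

#' Train the reconstructor on paired PPG/ECG segments
#'
#' Minimizes per-timestep mean squared error with Adam (batch size 1) plus
#' the L1/L2 kernel penalty; stops at `max_epochs` or when the validation
#' loss has not improved for `early_stop_patience` epochs, restoring the
#' best-validation parameters.
#'
#' @param model A [build_reconstructor()] result.
#' @param train_set,val_set `segment_set`s (PPG in, ECG target) from
#'   [split_pair()].
#' @return The trained `reconstructor`, with `history` (tibble of per-epoch
#'   train/validation loss), `best_epoch`, `epochs_run` filled in.
#' @export
train_reconstructor <- function(model, train_set, val_set = NULL) {
  stopifnot(inherits(model, "reconstructor"),
            inherits(train_set, "segment_set"))
  if (nrow(train_set$ppg) == 0) stop("empty training set", call. = FALSE)
  if (ncol(train_set$ppg) != model$input_length) {
    stop("training window length ", ncol(train_set$ppg),
         " != model input_length ", model$input_length, call. = FALSE)
  }
  Xval <- matrix(numeric(0), 0, model$input_length)
  Yval <- Xval
  if (!is.null(val_set)) {
    stopifnot(inherits(val_set, "segment_set"))
    Xval <- val_set$ppg
    Yval <- val_set$ecg
  }
  cfg <- model$config
  fit <- bilstm_train(model$params, cfg$hidden_units,
                      train_set$ppg, train_set$ecg, Xval, Yval,
                      cfg$max_epochs, cfg$learning_rate, cfg$l1, cfg$l2,
                      cfg$early_stop_patience, cfg$seed + 1L,
                      cfg$shuffle)
  model$params <- fit$params
  model$trained <- TRUE
  model$history <- tibble::tibble(
    epoch = seq_along(fit$train_loss),
    train_loss = fit$train_loss,
    val_loss = fit$val_loss)
  model$best_epoch <- fit$best_epoch
  model$epochs_run <- fit$epochs_run
  model$best_val_loss <- fit$best_val_loss
  model
}

#' Reconstruct ECG windows from PPG windows
#'
#' @param model A trained (or freshly built) `reconstructor`.
#' @param ppg_segments A `segment_set` or a numeric matrix with one PPG
#'   window per row; window length must equal the model's `input_length`.
#' @return Numeric matrix of reconstructed ECG windows (mV), one per row,
#'   order preserved.
#' @export
reconstruct <- function(model, ppg_segments) {
  stopifnot(inherits(model, "reconstructor"))
  X <- if (inherits(ppg_segments, "segment_set")) ppg_segments$ppg
       else as.matrix(ppg_segments)
  if (nrow(X) == 0) {
    return(matrix(numeric(0), 0, model$input_length))
  }
  if (ncol(X) != model$input_length) {
    stop("window length ", ncol(X), " != model input_length ",
         model$input_length, call. = FALSE)
  }
  bilstm_predict(model$params, model$config$hidden_units, X)
}

#' @export
print.reconstructor <- function(x, ...) {
  cat(sprintf(
    "<reconstructor> BiLSTM %d units/direction, input %d samples, %s\n",
    x$config$hidden_units, x$input_length,
    if (x$trained) sprintf("trained (%d epochs, best %d)",
                           x$epochs_run, x$best_epoch)
    else "untrained"))
  invisible(x)
}

#' Per-epoch loss history of a trained reconstructor
#'
#' @param x A trained `reconstructor`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `train_loss`, `val_loss`.
#' @importFrom generics tidy
#' @export
tidy.reconstructor <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has no training history (untrained)", call. = FALSE)
  }
  x$history
}

#' One-row summary of a trained reconstructor
#'
#' @param x A trained `reconstructor`.
#' @param ... Unused.
#' @return Tibble with hidden units, epochs run, best epoch, best
#'   validation loss.
#' @importFrom generics glance
#' @export
glance.reconstructor <- function(x, ...) {
  tibble::tibble(
    hidden_units = x$config$hidden_units,
    input_length = x$input_length,
    trained = x$trained,
    epochs_run = x$epochs_run %||% NA_integer_,
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_loss = x$best_val_loss %||% NA_real_)
}

#' @export
generics::tidy

#' @export
generics::glance

#' Plot the training history
#'
#' @param object A trained `reconstructor`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss against epoch (log scale).
#' @export
autoplot.reconstructor <- function(object, ...) {
  h <- tidy(object) |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (mV^2)", colour = NULL)
}

#' Save / load a reconstructor as plain text
#'
#' The fitted state is written as JSON (config, input length, flat
#' parameter vector at full precision), so models survive text-only
#' round-trips.
#'
#' @param model A `reconstructor`.
#' @param path File path (JSON).
#' @return `save_reconstructor`: `path`, invisibly. `load_reconstructor`:
#'   the restored `reconstructor`.
#' @export
save_reconstructor <- function(model, path) {
  stopifnot(inherits(model, "reconstructor"))
  obj <- list(config = unclass(model$config),
              input_length = model$input_length,
              trained = model$trained,
              params = model$params,
              history = model$history,
              best_epoch = model$best_epoch,
              epochs_run = model$epochs_run)
  # digits = I(17): 17 significant digits round-trip doubles bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_reconstructor
#' @export
load_reconstructor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(reconstructor_config,
                 obj$config[setdiff(names(obj$config), "loss")])
  model <- build_reconstructor(cfg, obj$input_length)
  model$params <- as.numeric(obj$params)
  model$trained <- isTRUE(obj$trained)
  if (!is.null(obj$history)) model$history <- tibble::as_tibble(obj$history)
  model$best_epoch <- obj$best_epoch
  model$epochs_run <- obj$epochs_run
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
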