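# small helper: wrap matrices as a 1-s segment_set (fs = window length)
seg_set <- function(ppg, ecg, role = "train") {
  ecgrecon:::new_segment_set(as.numeric(t(ecg)), as.numeric(t(ppg)),
                             role, segment_s = 1, fs = ncol(ppg))
}

test_that("builds with equal seeds are identical; config is validated", {
  a <- build_reconstructor(reconstructor_config(seed = 4), 50)
  b <- build_reconstructor(reconstructor_config(seed = 4), 50)
  expect_identical(a$params, b$params)
  c2 <- build_reconstructor(reconstructor_config(seed = 5), 50)
  expect_false(identical(a$params, c2$params))
  expect_error(reconstructor_config(hidden_units = 0), "positive")
  expect_error(reconstructor_config(batch_size = 4), "batch_size")
  expect_error(build_reconstructor(input_length = 0), "input_length")
})

test_that("an untrained model predicts finite sequences of input length", {
  m <- build_reconstructor(reconstructor_config(hidden_units = 5, seed = 1),
                           40)
  X <- matrix(runif(3 * 40), 3, 40)
  Y <- reconstruct(m, X)
  expect_equal(dim(Y), c(3, 40))
  expect_true(all(is.finite(Y)))
  expect_error(reconstruct(m, matrix(0, 2, 39)), "input_length")
  expect_equal(dim(reconstruct(m, matrix(0, 0, 40))), c(0, 40))
})

test_that("BPTT gradients agree with finite differences", {
  h <- 3
  p <- ecgrecon:::bilstm_init_params(h, 11)
  set.seed(2)
  x <- runif(7)
  y <- rnorm(7)
  an <- ecgrecon:::bilstm_loss_grad(p, h, x, y, 1e-4, 1e-4)
  eps <- 1e-6
  num <- vapply(seq_along(p), function(k) {
    up <- replace(p, k, p[k] + eps)
    dn <- replace(p, k, p[k] - eps)
    (ecgrecon:::bilstm_loss_grad(up, h, x, y, 1e-4, 1e-4)$loss -
       ecgrecon:::bilstm_loss_grad(dn, h, x, y, 1e-4, 1e-4)$loss) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - an$grad)), 1e-6)
})

test_that("training on a constant-zero target converges to zero output", {
  set.seed(7)
  ppg <- matrix(runif(6 * 30), 6, 30)
  ecg <- matrix(0, 6, 30)
  m <- build_reconstructor(
    reconstructor_config(hidden_units = 8, max_epochs = 150,
                         early_stop_patience = 0, seed = 2), 30)
  fit <- train_reconstructor(m, seg_set(ppg[1:4, ], ecg[1:4, ]),
                             seg_set(ppg[5:6, ], ecg[5:6, ], role = "validation"))
  pred <- reconstruct(fit, ppg[5:6, ])
  expect_lt(sqrt(mean(pred^2)), 0.01)
})

test_that("training is seed-deterministic including history", {
  set.seed(9)
  ppg <- matrix(runif(4 * 25), 4, 25)
  ecg <- matrix(rnorm(4 * 25, sd = 0.1), 4, 25)
  run <- function() {
    m <- build_reconstructor(
      reconstructor_config(hidden_units = 6, max_epochs = 20,
                           early_stop_patience = 0, seed = 3), 25)
    train_reconstructor(m, seg_set(ppg, ecg))
  }
  a <- run()
  b <- run()
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
  expect_identical(reconstruct(a, ppg), reconstruct(b, ppg))
})

test_that("early stopping restores the best-validation parameters", {
  set.seed(13)
  ppg <- matrix(runif(6 * 20), 6, 20)
  ecg <- 0.5 * ppg + matrix(rnorm(6 * 20, sd = 0.05), 6, 20)
  m <- build_reconstructor(
    reconstructor_config(hidden_units = 4, max_epochs = 400,
                         early_stop_patience = 10, seed = 5), 20)
  fit <- train_reconstructor(m, seg_set(ppg[1:4, ], ecg[1:4, ]),
                             seg_set(ppg[5:6, ], ecg[5:6, ], role = "validation"))
  expect_lt(fit$epochs_run, 400)
  h <- tidy(fit)
  expect_equal(fit$best_epoch, which.min(h$val_loss))
  expect_equal(fit$best_val_loss, min(h$val_loss))
})

test_that("empty or mismatched training sets are rejected", {
  m <- build_reconstructor(reconstructor_config(seed = 1), 20)
  empty <- seg_set(matrix(0, 0, 20), matrix(0, 0, 20))
  expect_error(train_reconstructor(m, empty), "empty")
  wrong <- seg_set(matrix(0, 2, 10), matrix(0, 2, 10))
  expect_error(train_reconstructor(m, wrong), "input_length")
})

test_that("models survive a plain-text save/load round trip", {
  set.seed(15)
  ppg <- matrix(runif(3 * 15), 3, 15)
  ecg <- matrix(rnorm(3 * 15, sd = 0.2), 3, 15)
  m <- build_reconstructor(
    reconstructor_config(hidden_units = 4, max_epochs = 10,
                         early_stop_patience = 0, seed = 6), 15)
  fit <- train_reconstructor(m, seg_set(ppg, ecg))
  path <- withr::local_tempfile(fileext = ".json")
  save_reconstructor(fit, path)
  back <- load_reconstructor(path)
  expect_identical(back$params, fit$params)
  expect_identical(reconstruct(back, ppg), reconstruct(fit, ppg))
  expect_equal(glance(back)$best_epoch, glance(fit)$best_epoch)
})
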