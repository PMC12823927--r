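# ADAM training in the two input modes. Individual mode is standard
# shuffled minibatch regression on (genotype row, trait) pairs. Summary mode
# treats the single (LD input, training-trait vector) pair as the whole
# training set: one gradient step per epoch, loss averaged over the n_tr
# output units.

#' Training settings
#'
#' @param epochs Number of epochs. In summary mode each epoch is exactly one
#'   gradient step on the single LD example.
#' @param batch_size Minibatch size for individual mode; recorded but inert
#'   in summary mode (the training set is one example).
#' @param initial_lr Initial learning rate.
#' @param decay_rate Per-epoch multiplicative learning-rate decay in (0, 1].
#' @param optimizer Only `"adam"` is provided.
#' @param seed Seed controlling batch shuffling and dropout.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 256L, initial_lr = 0.001,
                         decay_rate = 0.96, optimizer = "adam", seed = 1L) {
  structure(list(epochs = assert_count(epochs, "epochs"),
                 batch_size = assert_count(batch_size, "batch_size"),
                 initial_lr = assert_number(initial_lr, "initial_lr", 0,
                                            strict_lower = TRUE),
                 decay_rate = assert_number(decay_rate, "decay_rate", 0, 1,
                                            strict_lower = TRUE),
                 optimizer = match.arg(optimizer, "adam"),
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "train_config")
}

#' Named training presets matching the model presets
#'
#' `"dnn-paper"`: 100 epochs, batch 256, lr 0.001, decay 0.96.
#' `"cnn-paper"`: 200 epochs, batch 32, lr 0.1, decay 0.98.
#' `"lstm-paper"`: 10 epochs, batch 256, lr 0.001, decay 0.96.
#' `"bilstm-paper"`: 5 epochs, batch 256, lr 0.001, decay 0.96.
#' `"transformer-paper"`: 10 epochs, batch 8, lr 0.001, decay 0.96.
#'
#' @param name Preset name.
#' @param seed Seed passed through to [train_config()].
#' @return A `train_config`.
#' @export
train_preset <- function(name, seed = 1L) {
  switch(name,
    "dnn-paper" = train_config(100L, 256L, 0.001, 0.96, seed = seed),
    "cnn-paper" = train_config(200L, 32L, 0.1, 0.98, seed = seed),
    "lstm-paper" = train_config(10L, 256L, 0.001, 0.96, seed = seed),
    "bilstm-paper" = train_config(5L, 256L, 0.001, 0.96, seed = seed),
    "transformer-paper" = train_config(10L, 8L, 0.001, 0.96, seed = seed),
    stop_ldrisk("unknown training preset: ", name))
}

# model preset name -> its training preset
default_train_preset <- function(model_name) {
  switch(sub("-.*", "", model_name),
         dnn = "dnn-paper", cnn = "cnn-paper", lstm = "lstm-paper",
         bilstm = "bilstm-paper", transformer = "transformer-paper")
}

#' Mean squared error loss
#'
#' `L(O, Y) = (1/n) sum (O_i - Y_i)^2`, the loss minimized in both training
#' modes.
#'
#' @param outputs,targets Equal-length numeric vectors.
#' @return A single number.
#' @examples
#' mse_loss(c(1, 2), c(0, 0))  # 2.5
#' @export
mse_loss <- function(outputs, targets) {
  if (length(outputs) != length(targets)) {
    stop_ldrisk("outputs and targets must have equal length")
  }
  mean((outputs - targets)^2)
}

#' Learning rate at a given epoch
#'
#' Exponential per-epoch decay: `initial_lr * decay_rate^epoch` (epoch 0 is
#' the first).
#'
#' @param config A [train_config()].
#' @param epoch Zero-based epoch index.
#' @return Learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  stopifnot(inherits(config, "train_config"))
  if (any(epoch < 0)) stop_ldrisk("epoch must be >= 0")
  config$initial_lr * config$decay_rate^epoch
}

# ---- ADAM ------------------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    lapply(l$params, function(p) list(m = array(0, dim(p) %||% length(p)),
                                      v = array(0, dim(p) %||% length(p))))
  })
}

adam_step <- function(model, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  for (k in seq_along(model$layers)) {
    for (nm in names(grads[[k]])) {
      g <- grads[[k]][[nm]]
      s <- state[[k]][[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      model$layers[[k]]$params[[nm]] <-
        model$layers[[k]]$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[k]][[nm]] <- s
    }
  }
  list(model = model, state = state)
}

new_fit_result <- function(model, loss_history, final_train_error, mode) {
  structure(list(model = model, loss_history = loss_history,
                 final_train_error = final_train_error, mode = mode),
            class = "ldrisk_fit")
}

#' @export
print.ldrisk_fit <- function(x, ...) {
  cat(sprintf("ldrisk_fit (%s mode, '%s'): %d epochs, final training MSE %.4g\n",
              x$mode, x$model$spec$name, length(x$loss_history),
              x$final_train_error))
  invisible(x)
}

# gradient of the mean-over-everything squared error wrt outputs
mse_grad <- function(out, target_mat) 2 * (out - target_mat) / length(out)

#' Fit a model on individual-level data
#'
#' Shuffled minibatch ADAM training of a one-output model on (standardized
#' genotype row, trait) pairs, with exponential learning-rate decay per
#' epoch. Deterministic given `config$seed`.
#'
#' @param model An individual-mode `ldrisk_model` (`output_dim` 1).
#' @param x Training inputs: `std_genotypes` or numeric matrix rows.
#' @param y Numeric training trait values, one per row of `x`.
#' @param config A [train_config()].
#' @return An `ldrisk_fit` with the trained model, per-epoch `loss_history`,
#'   and `final_train_error` (training MSE recomputed in evaluation mode
#'   after the last step).
#' @export
fit_individual <- function(model, x, y, config) {
  stopifnot(inherits(model, "ldrisk_model"), inherits(config, "train_config"))
  if (model$spec$output_dim != 1L) {
    stop_ldrisk("fit_individual() needs an individual-mode model (output_dim 1)")
  }
  xt <- prepare_model_input(model$spec, x)
  n <- dim(xt)[1L]
  if (n != length(y)) stop_ldrisk("row count of x must match length(y)")
  set.seed(config$seed)
  state <- adam_init(model)
  loss_history <- numeric(config$epochs)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, ep - 1L)
    ord <- sample.int(n)
    starts <- seq.int(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- slice_batch(xt, idx)
      fw <- model_forward(model, xb, training = TRUE)
      out <- fw$out
      loss <- mean((out - y[idx])^2)
      if (!is.finite(loss)) {
        stop_ldrisk(sprintf("non-finite loss at epoch %d (lr %.3g); training aborted",
                            ep, lr))
      }
      ep_loss <- ep_loss + loss * length(idx)
      dout <- mse_grad(out, matrix(y[idx], length(idx), 1L))
      grads <- model_backward(model, fw$caches, dout)
      step <- step + 1L
      r <- adam_step(model, grads, state, lr, step)
      model <- r$model; state <- r$state
    }
    loss_history[ep] <- ep_loss / n
  }
  final <- mse_loss(drop(model_forward(model, xt, training = FALSE)$out), y)
  new_fit_result(model, loss_history, final, "individual")
}

slice_batch <- function(xt, idx) {
  nd <- length(dim(xt))
  if (nd == 2L) xt[idx, , drop = FALSE]
  else if (nd == 3L) xt[idx, , , drop = FALSE]
  else xt[idx, , , , drop = FALSE]
}

#' Fit a model on summary (LD) data
#'
#' The training set is the single pair (LD input, training trait vector):
#' the model has `n_tr` output units and each epoch performs one ADAM step
#' on the loss `L(O, Y) = (1/n_tr) sum (O_i - Y_i)^2`. No test data enters
#' fitting. Deterministic given `config$seed`.
#'
#' @param model A summary-mode `ldrisk_model` with `output_dim ==
#'   length(y)`.
#' @param ld_train An `ld_matrix` or `ld_block_set` from the training rows.
#' @param y Training trait values (length `n_tr`).
#' @param config A [train_config()]; `batch_size` is inert here.
#' @return An `ldrisk_fit`.
#' @export
fit_summary <- function(model, ld_train, y, config) {
  stopifnot(inherits(model, "ldrisk_model"), inherits(config, "train_config"))
  if (model$spec$input_mode != "summary") {
    stop_ldrisk("fit_summary() needs a summary-mode model")
  }
  if (model$spec$output_dim != length(y)) {
    stop_ldrisk(sprintf("model output_dim (%d) must equal length(y) (%d)",
                        model$spec$output_dim, length(y)))
  }
  xt <- prepare_model_input(model$spec, ld_train)
  set.seed(config$seed)
  state <- adam_init(model)
  loss_history <- numeric(config$epochs)
  target <- matrix(y, 1L, length(y))
  for (ep in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, ep - 1L)
    fw <- model_forward(model, xt, training = TRUE)
    out <- fw$out
    tgt <- target[rep(1L, nrow(out)), , drop = FALSE]
    loss <- mean((out - tgt)^2)
    if (!is.finite(loss)) {
      stop_ldrisk(sprintf("non-finite loss at epoch %d (lr %.3g); training aborted",
                          ep, lr))
    }
    loss_history[ep] <- loss
    dout <- mse_grad(out, tgt)
    grads <- model_backward(model, fw$caches, dout)
    r <- adam_step(model, grads, state, lr, ep)
    model <- r$model; state <- r$state
  }
  out <- model_forward(model, xt, training = FALSE)$out
  final <- mean((out - target[rep(1L, nrow(out)), , drop = FALSE])^2)
  new_fit_result(model, loss_history, final, "summary")
}
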