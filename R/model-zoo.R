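# Declarative model families and their named presets, for both
# individual-level inputs (genotype rows) and summary inputs (LD matrices,
# upper-triangle vectors, diagonal-block sets).

#' Describe a model architecture
#'
#' Low-level constructor pairing a model family with an ordered layer plan.
#' Most users will start from [model_preset()] instead.
#'
#' @param family One of `"dnn"`, `"cnn1d"`, `"cnn2d"`, `"lstm"`, `"bilstm"`,
#'   `"transformer"`.
#' @param input_mode `"individual"` (one output per sample) or `"summary"`
#'   (LD input; one output per *training* sample).
#' @param layer_plan List of internal layer descriptors, in order. The final
#'   output layer is appended automatically by [build_model()] and always has
#'   linear activation.
#' @param output_dim 1 for individual mode; the training-sample count for
#'   summary mode.
#' @param name Optional preset name, kept for reporting.
#' @param options List of family-specific settings (e.g. transformer window/
#'   stride, CNN block handling).
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(family, input_mode, layer_plan, output_dim = 1L,
                              name = NULL, options = list()) {
  family <- match.arg(family, c("dnn", "cnn1d", "cnn2d", "lstm", "bilstm",
                                "transformer"))
  input_mode <- match.arg(input_mode, c("individual", "summary"))
  if (length(layer_plan) == 0L) stop_ldrisk("layer_plan must be non-empty")
  output_dim <- assert_count(output_dim, "output_dim")
  structure(list(family = family, input_mode = input_mode,
                 layer_plan = layer_plan, output_dim = output_dim,
                 name = name %||% family, options = options),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("architecture_spec '%s': family %s, %s mode, %d layers + linear output (dim %d)\n",
              x$name, x$family, x$input_mode, length(x$layer_plan), x$output_dim))
  invisible(x)
}

#' List available model presets
#'
#' @return Character vector of preset names accepted by [model_preset()].
#' @export
list_model_presets <- function() {
  c("dnn-paper", "cnn-sim-s1", "cnn-sim-s2", "cnn-sim-s1-2d", "cnn-sim-s2-2d",
    "cnn-real-s1", "cnn-real-s2", "cnn-real-s1-2d", "cnn-real-s2-2d",
    "lstm-paper", "bilstm-paper", "transformer-paper")
}

dnn_plan <- function() {
  list(layer_dense(231L, "relu"), layer_dropout(0.2),
       layer_dense(77L, "relu"), layer_dense(22L, "relu"),
       layer_dropout(0.5), layer_dense(5L, "relu"))
}

cnn_dense_head <- function(n_hidden) {
  c(list(layer_flatten()),
    rep(list(layer_dense(50L, "relu")), n_hidden))
}

#' Construct one of the named reference architectures
#'
#' The presets reproduce the study's six model families:
#' \describe{
#'   \item{dnn-paper}{Dense 231-77-22-5 with dropout 0.2 after layer 1 and
#'     0.5 after layer 3. Individual mode consumes genotype rows; summary
#'     mode consumes the LD upper triangle.}
#'   \item{cnn-sim-s1 / cnn-sim-s2}{1D convolution, 50 filters of size 500,
#'     then 1 (S1) or 5 (S2) dense layers of 50 units; for wide simulated
#'     panels.}
#'   \item{cnn-sim-s1-2d / cnn-sim-s2-2d}{2D twins with 50 x 50 filters that
#'     read LD matrices/blocks as images.}
#'   \item{cnn-real-s1 / cnn-real-s2}{Compact variants for small panels:
#'     32 filters of size 5 (+ pool 2), S2 adding three 64 x 3 conv + pool
#'     stages; 2D twins use 5 x 5 / 3 x 3 kernels with 2 x 2 pooling.}
#'   \item{lstm-paper / bilstm-paper}{Five stacked LSTM layers of 10 units /
#'     two bidirectional layers of 10 units, then a dense layer. Individual
#'     mode reads the SNP sequence one value per timestep; summary mode reads
#'     LD row t as the step-t feature vector.}
#'   \item{transformer-paper}{Individual mode: sliding windows (default
#'     1000/500) -> position-wise embedding -> 6-head attention block ->
#'     outputs averaged across positions and windows -> feedforward of 64.
#'     Summary mode: flattened diagonal LD blocks embedded to 128, sinusoidal
#'     positional encoding, two 6-head attention blocks with dropout 0.1 and
#'     layer norm, then two dense 128 layers + dropout 0.1 + layer norm.}
#' }
#' Every preset ends in a linear output layer whose width is 1 in individual
#' mode and `n_train` in summary mode.
#'
#' @param name Preset name; see [list_model_presets()].
#' @param input_mode `"individual"` or `"summary"`.
#' @param n_train Training-sample count (required in summary mode).
#' @param window,stride Transformer individual-mode window settings.
#' @param strict_paper Drop the trailing partial window (see
#'   [window_slices()]).
#' @param blocks_as For CNN summary mode: `"average"` pools per-block
#'   features before the dense head (default); `"examples"` treats each block
#'   as its own example sharing the target.
#' @return An `architecture_spec`.
#' @examples
#' model_preset("dnn-paper")
#' model_preset("lstm-paper", input_mode = "summary", n_train = 100)
#' @export
model_preset <- function(name, input_mode = "individual", n_train = NULL,
                         window = 1000L, stride = 500L, strict_paper = FALSE,
                         blocks_as = c("average", "examples")) {
  input_mode <- match.arg(input_mode, c("individual", "summary"))
  blocks_as <- match.arg(blocks_as)
  output_dim <- if (input_mode == "summary") {
    if (is.null(n_train)) stop_ldrisk("summary mode needs `n_train`")
    assert_count(n_train, "n_train")
  } else 1L
  opts <- list(blocks_as = blocks_as)
  plan <- switch(name,
    "dnn-paper" = dnn_plan(),
    "cnn-sim-s1" = c(list(layer_conv1d(50L, 500L)), cnn_dense_head(1L)),
    "cnn-sim-s2" = c(list(layer_conv1d(50L, 500L)), cnn_dense_head(5L)),
    "cnn-sim-s1-2d" = c(list(layer_conv2d(50L, 50L)), cnn_dense_head(1L)),
    "cnn-sim-s2-2d" = c(list(layer_conv2d(50L, 50L)), cnn_dense_head(5L)),
    "cnn-real-s1" = c(list(layer_conv1d(32L, 5L), layer_maxpool1d(2L)),
                      cnn_dense_head(1L)),
    "cnn-real-s2" = c(list(layer_conv1d(32L, 5L), layer_maxpool1d(2L),
                           layer_conv1d(64L, 3L), layer_maxpool1d(2L),
                           layer_conv1d(64L, 3L), layer_maxpool1d(2L),
                           layer_conv1d(64L, 3L), layer_maxpool1d(2L)),
                      cnn_dense_head(5L)),
    "cnn-real-s1-2d" = c(list(layer_conv2d(32L, 5L), layer_maxpool2d(2L)),
                         cnn_dense_head(1L)),
    "cnn-real-s2-2d" = c(list(layer_conv2d(32L, 5L), layer_maxpool2d(2L),
                              layer_conv2d(64L, 3L), layer_maxpool2d(2L),
                              layer_conv2d(64L, 3L), layer_maxpool2d(2L),
                              layer_conv2d(64L, 3L), layer_maxpool2d(2L)),
                         cnn_dense_head(5L)),
    "lstm-paper" = c(rep(list(layer_lstm(10L, TRUE)), 4L),
                     list(layer_lstm(10L, FALSE))),
    "bilstm-paper" = list(layer_bilstm(10L, TRUE), layer_bilstm(10L, FALSE)),
    "transformer-paper" = if (input_mode == "individual") {
      opts$window <- as.integer(window)
      opts$stride <- as.integer(stride)
      opts$strict_paper <- strict_paper
      list(layer_embed(64L), layer_posenc(),
           layer_mha_block(6L, 64L, dropout = 0),
           layer_mean_tokens(), layer_window_merge(),
           layer_dense(64L, "relu"))
    } else {
      list(layer_embed(128L), layer_posenc(),
           layer_mha_block(6L, 128L, dropout = 0.1),
           layer_mha_block(6L, 128L, dropout = 0.1),
           layer_mean_tokens(),
           layer_dense(128L, "relu"), layer_dense(128L, "relu"),
           layer_dropout(0.1), layer_layernorm())
    },
    stop_ldrisk("unknown preset: ", name)
  )
  family <- switch(sub("-.*", "", name),
                   dnn = "dnn", lstm = "lstm", bilstm = "bilstm",
                   transformer = "transformer",
                   cnn = if (grepl("2d$", name)) "cnn2d" else "cnn1d")
  # summary-mode CNNs see the diagonal blocks as a batch of images; under the
  # default "average" convention the per-block features are pooled before the
  # dense head so any number of blocks maps to one summary example
  if (family %in% c("cnn1d", "cnn2d") && input_mode == "summary" &&
      blocks_as == "average") {
    flat_at <- which(vapply(plan, function(l) l$type == "flatten", logical(1)))
    plan <- append(plan, list(layer_mean_batch()), after = flat_at[1L])
  }
  architecture_spec(family, input_mode, plan, output_dim, name = name,
                    options = opts)
}

#' Build a trainable model from an architecture spec
#'
#' Initializes every layer in the spec's plan for the given input shape,
#' appends the linear output layer, and seeds the fan-based random
#' initialization so the build is reproducible.
#'
#' @param spec An [architecture_spec()].
#' @param input_shape Integer vector, the per-example input shape (no batch
#'   dimension): `p` for dense/sequence individual input, the upper-triangle
#'   length for summary DNN, `c(p, p)` for summary LSTM, `c(b, b)` block
#'   side for 2D CNN input, etc. See [prepare_model_input()] for how raw
#'   objects map to tensors.
#' @param seed Integer seed for weight initialization.
#' @return An `ldrisk_model`.
#' @examples
#' m <- build_model(model_preset("dnn-paper"), input_shape = 168, seed = 1)
#' @export
build_model <- function(spec, input_shape, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  set.seed(assert_count(seed, "seed", min = 0L))
  plan <- spec$layer_plan
  # transformer individual mode: prepend the window slicer now that p is known
  if (spec$family == "transformer" && spec$input_mode == "individual") {
    w <- window_slices(input_shape[1L], spec$options$window,
                       spec$options$stride,
                       strict_paper = isTRUE(spec$options$strict_paper))
    plan <- c(list(layer_window_slice(w)), plan)
  }
  shape <- normalize_input_shape(spec, input_shape)
  layers <- vector("list", length(plan) + 1L)
  nw <- 1L
  for (k in seq_along(plan)) {
    lay <- nn_build_layer(plan[[k]], shape)
    if (lay$type == "window_slice") nw <- lay$n_windows
    if (lay$type == "window_merge") lay$n_windows <- nw
    layers[[k]] <- lay
    shape <- lay$out_shape
  }
  if (length(shape) != 1L) {
    lay <- nn_build_layer(layer_flatten(), shape)
    layers[[length(plan) + 1L]] <- lay
    shape <- lay$out_shape
    layers <- c(layers, list(NULL))
  }
  out_layer <- nn_build_layer(layer_dense(spec$output_dim, "linear"), shape)
  layers[[length(layers)]] <- out_layer
  structure(list(spec = spec, layers = layers, input_shape = input_shape,
                 init_seed = as.integer(seed)),
            class = "ldrisk_model")
}

# the tensor shape fed to layer 1, given the user-facing input shape
normalize_input_shape <- function(spec, input_shape) {
  switch(spec$family,
    dnn = input_shape[1L],
    cnn1d = c(input_shape[1L], 1L),
    cnn2d = c(input_shape[1L], input_shape[2L], 1L),
    lstm = , bilstm = {
      if (spec$input_mode == "individual") c(input_shape[1L], 1L)
      else c(input_shape[1L], input_shape[2L])
    },
    transformer = {
      if (spec$input_mode == "individual") input_shape[1L]
      else c(input_shape[1L], input_shape[2L])   # tokens x flattened block
    })
}

#' @export
print.ldrisk_model <- function(x, ...) {
  cat(sprintf("ldrisk_model '%s' (%s mode): %d layers, %d parameters, input shape [%s]\n",
              x$spec$name, x$spec$input_mode, length(x$layers),
              n_parameters(x), paste(x$input_shape, collapse = " x ")))
  invisible(x)
}

#' Count trainable parameters of a model
#'
#' @param model An `ldrisk_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers,
             function(l) sum(vapply(l$params, length, numeric(1))),
             numeric(1)))
}

#' Convert a raw input object to the tensor a model consumes
#'
#' Maps the field's natural objects onto model tensors: a matrix of
#' standardized genotype rows for individual mode (reshaped per family), an
#' [compute_ld()] matrix for summary DNN (upper triangle) and LSTM (rows as
#' timestep features), and a [partition_blocks()] block set for summary CNN
#' (blocks as a batch of images) and transformer (flattened blocks as
#' tokens).
#'
#' @param spec An `architecture_spec`.
#' @param x A numeric matrix (samples x SNPs), `std_genotypes`, `ld_matrix`
#'   or `ld_block_set`.
#' @return Numeric array shaped for the model's first layer.
#' @export
prepare_model_input <- function(spec, x) {
  if (inherits(x, "std_genotypes")) x <- x$values
  if (spec$input_mode == "individual") {
    if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
    return(switch(spec$family,
      dnn = , transformer = x,
      cnn1d = , lstm = , bilstm = array(x, c(nrow(x), ncol(x), 1L)),
      cnn2d = stop_ldrisk("2D CNNs take summary (matrix) input")))
  }
  switch(spec$family,
    dnn = matrix(upper_triangle(x, include_diagonal = TRUE), nrow = 1L),
    lstm = , bilstm = {
      m <- if (inherits(x, "ld_matrix")) x$values else x
      array(m, c(1L, nrow(m), ncol(m)))
    },
    cnn2d = {
      if (!inherits(x, "ld_block_set")) x <- partition_blocks(x, ncol(x$values))
      b <- x$block_size
      arr <- array(0, c(x$n_blocks, b, b, 1L))
      for (k in seq_len(x$n_blocks)) arr[k, , , 1L] <- x$blocks[[k]]
      arr
    },
    cnn1d = stop_ldrisk("1D CNNs take individual-level input; use a 2D preset for LD matrices"),
    transformer = {
      if (!inherits(x, "ld_block_set")) x <- partition_blocks(x, ncol(x$values))
      b <- x$block_size
      arr <- array(0, c(1L, x$n_blocks, b * b))
      for (k in seq_len(x$n_blocks)) arr[1L, k, ] <- as.vector(x$blocks[[k]])
      arr
    })
}

# input_shape (for build_model) implied by a raw input object
infer_input_shape <- function(spec, x) {
  xt <- prepare_model_input(spec, x)
  d <- dim(xt)
  shape <- switch(spec$family,
    dnn = d[2L],
    cnn1d = d[2L],
    cnn2d = c(d[2L], d[3L]),
    lstm = , bilstm = if (spec$input_mode == "individual") d[2L] else c(d[2L], d[3L]),
    transformer = if (spec$input_mode == "individual") d[2L] else c(d[2L], d[3L]))
  shape
}

model_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (k in seq_along(model$layers)) {
    r <- nn_forward_layer(model$layers[[k]], x, training = training)
    caches[[k]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches)
}

model_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (k in rev(seq_along(model$layers))) {
    r <- nn_backward_layer(model$layers[[k]], caches[[k]], dout)
    grads[[k]] <- r$grads
    dout <- r$dx
  }
  grads
}

#' Predict from a fitted or freshly built model
#'
#' Runs a deterministic evaluation-mode forward pass (dropout disabled).
#' Individual-mode models return one value per input row; summary-mode
#' models return the `output_dim = n_train` outputs `O_1..O_n_tr` produced
#' from the LD input.
#'
#' @param object An `ldrisk_model`.
#' @param newdata Raw input accepted by [prepare_model_input()].
#' @param ... Unused.
#' @return Numeric vector of predictions (matrix when a summary CNN is built
#'   with `blocks_as = "examples"`).
#' @export
predict.ldrisk_model <- function(object, newdata, ...) {
  x <- prepare_model_input(object$spec, newdata)
  out <- model_forward(object, x, training = FALSE)$out
  if (object$spec$input_mode == "individual") return(drop(out))
  if (nrow(out) == 1L) drop(out) else out
}
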