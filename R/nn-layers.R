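# Native layer primitives with explicit forward/backward passes.
#
# A layer is a list(type, ...config, params = list(<numeric arrays>)).
# Shapes exclude the batch dimension: a dense layer sees a matrix n x d,
# conv1d/recurrent layers an array n x T x C, conv2d an array n x H x W x C.
# All of this is internal; the exported surface is the model zoo.

act_fwd <- function(name, z) {
  switch(name,
         linear = z,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         stop_ldrisk("unknown activation: ", name))
}

# dout * f'(z); `a` is the forward output (used where cheaper)
act_bwd <- function(name, z, a, dout) {
  switch(name,
         linear = dout,
         relu = dout * (z > 0),
         tanh = dout * (1 - a^2),
         sigmoid = dout * a * (1 - a),
         stop_ldrisk("unknown activation: ", name))
}

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dims)
}

# ---- layer constructors (pre-build descriptors) ----------------------------

#' Layer descriptors for custom architectures
#'
#' Building blocks for the `layer_plan` of an [architecture_spec()]:
#' fully connected (`layer_dense`), inverted dropout (`layer_dropout`),
#' flattening, 1D/2D valid convolutions with max pooling, (bidirectional)
#' LSTM, position-wise linear embedding, sinusoidal positional encoding, a
#' residual multi-head attention block with optional dropout and layer norm,
#' layer normalization, and the pooling helpers used by the transformer and
#' summary CNNs (`layer_mean_tokens` averages over sequence positions,
#' `layer_mean_batch` over a batch of blocks, `layer_window_slice` /
#' `layer_window_merge` fan a SNP sequence out into sliding windows and
#' average the per-window representations back). Descriptors are inert until
#' [build_model()] initializes them against an input shape.
#'
#' @param units,filters Layer width / number of convolution filters.
#' @param activation Hidden activation: `"linear"`, `"relu"`, `"tanh"`,
#'   `"sigmoid"`.
#' @param rate,dropout Dropout probability (active during fitting only).
#' @param kernel Convolution kernel length (1D) or side (2D, square).
#' @param pool Max-pooling window (non-overlapping).
#' @param return_sequences Emit the whole hidden sequence rather than the
#'   final state.
#' @param d_model Embedding/attention width.
#' @param heads Number of attention heads.
#' @param key_dim Per-head projection width; default `ceiling(d_model/heads)`.
#' @param layer_norm Apply layer normalization after the residual add.
#' @param windows A [window_slices()] tibble.
#' @return A layer descriptor list.
#' @name layers
NULL

#' @rdname layers
#' @export
layer_dense <- function(units, activation = "linear") {
  list(type = "dense", units = as.integer(units), activation = activation)
}
#' @rdname layers
#' @export
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
#' @rdname layers
#' @export
layer_flatten <- function() list(type = "flatten")
#' @rdname layers
#' @export
layer_conv1d <- function(filters, kernel, activation = "relu") {
  list(type = "conv1d", filters = as.integer(filters),
       kernel = as.integer(kernel), activation = activation)
}
#' @rdname layers
#' @export
layer_maxpool1d <- function(pool) list(type = "maxpool1d", pool = as.integer(pool))
#' @rdname layers
#' @export
layer_conv2d <- function(filters, kernel, activation = "relu") {
  list(type = "conv2d", filters = as.integer(filters),
       kernel = as.integer(kernel), activation = activation)
}
#' @rdname layers
#' @export
layer_maxpool2d <- function(pool) list(type = "maxpool2d", pool = as.integer(pool))
#' @rdname layers
#' @export
layer_lstm <- function(units, return_sequences = FALSE) {
  list(type = "lstm", units = as.integer(units),
       return_sequences = return_sequences)
}
#' @rdname layers
#' @export
layer_bilstm <- function(units, return_sequences = FALSE) {
  list(type = "bilstm", units = as.integer(units),
       return_sequences = return_sequences)
}
#' @rdname layers
#' @export
layer_embed <- function(d_model) list(type = "embed", d_model = as.integer(d_model))
#' @rdname layers
#' @export
layer_posenc <- function() list(type = "posenc")
#' @rdname layers
#' @export
layer_mha_block <- function(heads, d_model, key_dim = NULL, dropout = 0,
                            layer_norm = TRUE) {
  list(type = "mha_block", heads = as.integer(heads),
       d_model = as.integer(d_model),
       key_dim = as.integer(key_dim %||% max(1L, ceiling(d_model / heads))),
       dropout = dropout, layer_norm = layer_norm)
}
#' @rdname layers
#' @export
layer_layernorm <- function() list(type = "layernorm")
#' @rdname layers
#' @export
layer_mean_tokens <- function() list(type = "mean_tokens")
#' @rdname layers
#' @export
layer_mean_batch <- function() list(type = "mean_batch")
#' @rdname layers
#' @export
layer_window_slice <- function(windows) list(type = "window_slice", windows = windows)
#' @rdname layers
#' @export
layer_window_merge <- function() list(type = "window_merge")

# ---- build: parameter init + shape inference -------------------------------

# in_shape excludes batch; returns layer with $params and $out_shape
nn_build_layer <- function(layer, in_shape) {
  out <- layer
  out$in_shape <- in_shape
  switch(layer$type,
    dense = {
      if (length(in_shape) != 1L) stop_ldrisk("dense layer needs flat input")
      out$params <- list(W = glorot(in_shape, layer$units),
                         b = numeric(layer$units))
      out$out_shape <- layer$units
    },
    dropout = , posenc = , layernorm = , mean_batch = , window_merge = {
      out$out_shape <- in_shape
      out$params <- list()
      if (layer$type == "layernorm") {
        d <- in_shape[length(in_shape)]
        out$params <- list(gamma = rep(1, d), beta = numeric(d))
      }
    },
    flatten = {
      out$out_shape <- prod(in_shape)
      out$params <- list()
    },
    conv1d = {
      if (length(in_shape) != 2L) stop_ldrisk("conv1d needs (length, channels) input")
      L <- in_shape[1L]; C <- in_shape[2L]; K <- layer$kernel
      if (K > L) stop_ldrisk("conv1d kernel longer than input")
      out$params <- list(W = glorot(K * C, layer$filters),
                         b = numeric(layer$filters))
      out$out_shape <- c(L - K + 1L, layer$filters)
    },
    maxpool1d = {
      L <- in_shape[1L]
      if (L < layer$pool) stop_ldrisk("pool size exceeds input length")
      out$out_shape <- c(L %/% layer$pool, in_shape[2L])
      out$params <- list()
    },
    conv2d = {
      if (length(in_shape) != 3L) stop_ldrisk("conv2d needs (H, W, channels) input")
      H <- in_shape[1L]; W <- in_shape[2L]; C <- in_shape[3L]; K <- layer$kernel
      if (K > H || K > W) stop_ldrisk("conv2d kernel larger than input")
      out$params <- list(W = glorot(K * K * C, layer$filters),
                         b = numeric(layer$filters))
      out$out_shape <- c(H - K + 1L, W - K + 1L, layer$filters)
    },
    maxpool2d = {
      if (min(in_shape[1:2]) < layer$pool) {
        stop_ldrisk("pool size exceeds input dimensions")
      }
      out$out_shape <- c(in_shape[1L] %/% layer$pool,
                         in_shape[2L] %/% layer$pool, in_shape[3L])
      out$params <- list()
    },
    lstm = {
      Fdim <- in_shape[2L]; H <- layer$units
      out$params <- lstm_init(Fdim, H)
      out$out_shape <- if (layer$return_sequences) c(in_shape[1L], H) else H
    },
    bilstm = {
      Fdim <- in_shape[2L]; H <- layer$units
      fw <- lstm_init(Fdim, H); bw <- lstm_init(Fdim, H)
      names(fw) <- paste0(names(fw), "_fw"); names(bw) <- paste0(names(bw), "_bw")
      out$params <- c(fw, bw)
      out$out_shape <- if (layer$return_sequences) c(in_shape[1L], 2L * H) else 2L * H
    },
    embed = {
      Fdim <- if (length(in_shape) == 1L) 1L else in_shape[2L]
      out$feat_dim <- Fdim
      out$params <- list(W = glorot(Fdim, layer$d_model),
                         b = numeric(layer$d_model))
      out$out_shape <- c(in_shape[1L], layer$d_model)
    },
    mha_block = {
      d <- layer$d_model; hk <- layer$heads * layer$key_dim
      if (in_shape[2L] != d) stop_ldrisk("mha_block input dim != d_model")
      out$params <- list(Wq = glorot(d, hk), bq = numeric(hk),
                         Wk = glorot(d, hk), bk = numeric(hk),
                         Wv = glorot(d, hk), bv = numeric(hk),
                         Wo = glorot(hk, d), bo = numeric(d),
                         gamma = rep(1, d), beta = numeric(d))
      out$out_shape <- in_shape
    },
    mean_tokens = {
      out$out_shape <- in_shape[2L]
      out$params <- list()
    },
    window_slice = {
      out$n_windows <- nrow(layer$windows)
      out$wlen <- layer$windows$end[1L] - layer$windows$start[1L] + 1L
      out$out_shape <- out$wlen
      out$params <- list()
    },
    stop_ldrisk("unknown layer type: ", layer$type)
  )
  out
}

lstm_init <- function(Fdim, H) {
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1            # forget-gate bias starts open
  list(Wx = glorot(Fdim, 4L * H), Wh = glorot(H, 4L * H), b = b)
}

posenc_table <- function(Tlen, d) {
  pos <- matrix(0:(Tlen - 1L), Tlen, d)
  j <- matrix(seq_len(d), Tlen, d, byrow = TRUE)
  i2 <- 2 * ((j - 1L) %/% 2L)
  angle <- pos / 10000^(i2 / d)
  ifelse(j %% 2L == 1L, sin(angle), cos(angle))
}

# ---- forward ---------------------------------------------------------------

nn_forward_layer <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      z <- sweep(x %*% layer$params$W, 2L, layer$params$b, "+")
      a <- act_fwd(layer$activation, z)
      list(out = a, cache = list(x = x, z = z, a = a))
    },
    dropout = {
      if (!training || layer$rate == 0) {
        list(out = x, cache = NULL)
      } else {
        mask <- array((stats::runif(length(x)) >= layer$rate) / (1 - layer$rate),
                      dim(x) %||% length(x))
        list(out = x * mask, cache = list(mask = mask))
      }
    },
    flatten = {
      n <- dim(x)[1L]
      list(out = matrix(x, n), cache = list(dims = dim(x)))
    },
    conv1d = conv1d_fwd(layer, x),
    maxpool1d = maxpool1d_fwd(layer, x),
    conv2d = conv2d_fwd(layer, x),
    maxpool2d = maxpool2d_fwd(layer, x),
    lstm = {
      r <- lstm_core_fwd(x, layer$params$Wx, layer$params$Wh, layer$params$b,
                         layer$return_sequences)
      list(out = r$out, cache = r)
    },
    bilstm = bilstm_fwd(layer, x),
    embed = embed_fwd(layer, x),
    posenc = {
      # table depends only on (T, d), so sequence length may vary per input
      d <- dim(x)
      tab <- posenc_table(d[2L], d[3L])
      pe <- aperm(array(tab, c(dim(tab), d[1L])), c(3L, 1L, 2L))
      list(out = x + pe, cache = NULL)
    },
    layernorm = layernorm_fwd(layer$params, x),
    mha_block = mha_fwd(layer, x, training),
    mean_tokens = {
      d <- dim(x)
      out <- matrix(0, d[1L], d[3L])
      for (t in seq_len(d[2L])) out <- out + matrix(x[, t, ], d[1L], d[3L])
      list(out = out / d[2L], cache = list(dims = d))
    },
    mean_batch = {
      list(out = matrix(colMeans(x), 1L), cache = list(m = nrow(x)))
    },
    window_slice = {
      w <- layer$windows; n <- nrow(x); nw <- nrow(w)
      out <- matrix(0, n * nw, layer$wlen)
      for (k in seq_len(nw)) {
        out[((k - 1L) * n + 1L):(k * n), ] <- x[, w$start[k]:w$end[k], drop = FALSE]
      }
      list(out = out, cache = list(n = n, p = ncol(x)))
    },
    window_merge = {
      nw <- layer$n_windows %||% stop_ldrisk("window_merge needs window count")
      n <- nrow(x) / nw
      out <- matrix(0, n, ncol(x))
      for (k in seq_len(nw)) {
        out <- out + x[((k - 1L) * n + 1L):(k * n), , drop = FALSE]
      }
      list(out = out / nw, cache = list(n = n, nw = nw))
    },
    stop_ldrisk("unknown layer type: ", layer$type)
  )
}

# ---- backward --------------------------------------------------------------

# returns list(dx, grads) with grads matching names(layer$params)
nn_backward_layer <- function(layer, cache, dout) {
  switch(layer$type,
    dense = {
      dz <- act_bwd(layer$activation, cache$z, cache$a, dout)
      list(dx = tcrossprod(dz, layer$params$W),
           grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
    },
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask, grads = list())
    },
    flatten = list(dx = array(dout, cache$dims), grads = list()),
    conv1d = conv1d_bwd(layer, cache, dout),
    maxpool1d = maxpool1d_bwd(layer, cache, dout),
    conv2d = conv2d_bwd(layer, cache, dout),
    maxpool2d = maxpool2d_bwd(layer, cache, dout),
    lstm = {
      r <- lstm_core_bwd(cache, dout, layer$params$Wx, layer$params$Wh,
                         layer$return_sequences)
      list(dx = r$dx, grads = list(Wx = r$dWx, Wh = r$dWh, b = r$db))
    },
    bilstm = bilstm_bwd(layer, cache, dout),
    embed = embed_bwd(layer, cache, dout),
    posenc = list(dx = dout, grads = list()),
    layernorm = layernorm_bwd(layer$params, cache, dout),
    mha_block = mha_bwd(layer, cache, dout),
    mean_tokens = {
      d <- cache$dims
      dx <- array(0, d)
      for (t in seq_len(d[2L])) dx[, t, ] <- dout / d[2L]
      list(dx = dx, grads = list())
    },
    mean_batch = {
      list(dx = matrix(dout, cache$m, length(dout), byrow = TRUE) / cache$m,
           grads = list())
    },
    window_slice = {
      w <- layer$windows; n <- cache$n
      dx <- matrix(0, n, cache$p)
      for (k in seq_len(nrow(w))) {
        dx[, w$start[k]:w$end[k]] <- dx[, w$start[k]:w$end[k]] +
          dout[((k - 1L) * n + 1L):(k * n), , drop = FALSE]
      }
      list(dx = dx, grads = list())
    },
    window_merge = {
      n <- cache$n; nw <- cache$nw
      dx <- matrix(0, n * nw, ncol(dout))
      for (k in seq_len(nw)) {
        dx[((k - 1L) * n + 1L):(k * n), ] <- dout / nw
      }
      list(dx = dx, grads = list())
    },
    stop_ldrisk("unknown layer type: ", layer$type)
  )
}

# ---- convolution / pooling internals ---------------------------------------

conv1d_im2col <- function(x, K) {
  d <- dim(x); n <- d[1L]; L <- d[2L]; C <- d[3L]
  Lo <- L - K + 1L
  Xc <- matrix(0, n * Lo, K * C)
  for (k in seq_len(K)) {
    blk <- x[, k:(k + Lo - 1L), , drop = FALSE]
    Xc[, ((k - 1L) * C + 1L):(k * C)] <- matrix(blk, n * Lo, C)
  }
  Xc
}

conv1d_fwd <- function(layer, x) {
  d <- dim(x); n <- d[1L]; C <- d[3L]; K <- layer$kernel
  Lo <- d[2L] - K + 1L
  Xc <- conv1d_im2col(x, K)
  z <- sweep(Xc %*% layer$params$W, 2L, layer$params$b, "+")
  a <- act_fwd(layer$activation, z)
  list(out = array(a, c(n, Lo, layer$filters)),
       cache = list(Xc = Xc, z = z, a = a, dims = d))
}

conv1d_bwd <- function(layer, cache, dout) {
  d <- cache$dims; n <- d[1L]; L <- d[2L]; C <- d[3L]; K <- layer$kernel
  Lo <- L - K + 1L
  dz <- act_bwd(layer$activation, cache$z, cache$a,
                matrix(dout, n * Lo, layer$filters))
  dW <- crossprod(cache$Xc, dz)
  db <- colSums(dz)
  dXc <- tcrossprod(dz, layer$params$W)
  dx <- array(0, d)
  for (k in seq_len(K)) {
    dx[, k:(k + Lo - 1L), ] <- dx[, k:(k + Lo - 1L), , drop = FALSE] +
      array(dXc[, ((k - 1L) * C + 1L):(k * C)], c(n, Lo, C))
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

maxpool1d_fwd <- function(layer, x) {
  d <- dim(x); n <- d[1L]; L <- d[2L]; C <- d[3L]; s <- layer$pool
  Lo <- L %/% s
  A <- array(x[, seq_len(Lo * s), , drop = FALSE], c(n, s, Lo, C))
  cur <- array(A[, 1L, , , drop = FALSE], c(n, Lo, C))
  arg <- array(1L, c(n, Lo, C))
  for (t in seq_len(s)[-1L]) {
    At <- array(A[, t, , , drop = FALSE], c(n, Lo, C))
    upd <- At > cur
    cur[upd] <- At[upd]
    arg[upd] <- t
  }
  list(out = cur, cache = list(arg = arg, dims = d))
}

maxpool1d_bwd <- function(layer, cache, dout) {
  d <- cache$dims; n <- d[1L]; L <- d[2L]; C <- d[3L]; s <- layer$pool
  Lo <- L %/% s
  dA <- array(0, c(n, s, Lo, C))
  for (t in seq_len(s)) {
    tmp <- array(0, c(n, Lo, C))
    sel <- cache$arg == t
    tmp[sel] <- dout[sel]
    dA[, t, , ] <- tmp
  }
  dx <- array(0, d)
  dx[, seq_len(Lo * s), ] <- array(dA, c(n, Lo * s, C))
  list(dx = dx, grads = list())
}

conv2d_im2col <- function(x, K) {
  d <- dim(x); n <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  Ho <- H - K + 1L; Wo <- W - K + 1L
  Xc <- matrix(0, n * Ho * Wo, K * K * C)
  for (kk in seq_len(K * K)) {
    dy <- ((kk - 1L) %% K) + 1L
    dz <- ((kk - 1L) %/% K) + 1L
    blk <- x[, dy:(dy + Ho - 1L), dz:(dz + Wo - 1L), , drop = FALSE]
    Xc[, ((kk - 1L) * C + 1L):(kk * C)] <- matrix(blk, n * Ho * Wo, C)
  }
  Xc
}

conv2d_fwd <- function(layer, x) {
  d <- dim(x); n <- d[1L]; K <- layer$kernel
  Ho <- d[2L] - K + 1L; Wo <- d[3L] - K + 1L
  Xc <- conv2d_im2col(x, K)
  z <- sweep(Xc %*% layer$params$W, 2L, layer$params$b, "+")
  a <- act_fwd(layer$activation, z)
  list(out = array(a, c(n, Ho, Wo, layer$filters)),
       cache = list(Xc = Xc, z = z, a = a, dims = d))
}

conv2d_bwd <- function(layer, cache, dout) {
  d <- cache$dims; n <- d[1L]; C <- d[4L]; K <- layer$kernel
  Ho <- d[2L] - K + 1L; Wo <- d[3L] - K + 1L
  dz <- act_bwd(layer$activation, cache$z, cache$a,
                matrix(dout, n * Ho * Wo, layer$filters))
  dW <- crossprod(cache$Xc, dz)
  db <- colSums(dz)
  dXc <- tcrossprod(dz, layer$params$W)
  dx <- array(0, d)
  for (kk in seq_len(K * K)) {
    dy <- ((kk - 1L) %% K) + 1L
    dzo <- ((kk - 1L) %/% K) + 1L
    dx[, dy:(dy + Ho - 1L), dzo:(dzo + Wo - 1L), ] <-
      dx[, dy:(dy + Ho - 1L), dzo:(dzo + Wo - 1L), , drop = FALSE] +
      array(dXc[, ((kk - 1L) * C + 1L):(kk * C)], c(n, Ho, Wo, C))
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

maxpool2d_fwd <- function(layer, x) {
  d <- dim(x); n <- d[1L]; C <- d[4L]; s <- layer$pool
  Ho <- d[2L] %/% s; Wo <- d[3L] %/% s
  A <- array(x[, seq_len(Ho * s), seq_len(Wo * s), , drop = FALSE],
             c(n, s, Ho, s, Wo, C))
  cur <- NULL; arg <- NULL
  for (t2 in seq_len(s)) for (t1 in seq_len(s)) {
    At <- array(A[, t1, , t2, , , drop = FALSE], c(n, Ho, Wo, C))
    code <- t1 + (t2 - 1L) * s
    if (is.null(cur)) {
      cur <- At; arg <- array(code, c(n, Ho, Wo, C))
    } else {
      upd <- At > cur
      cur[upd] <- At[upd]
      arg[upd] <- code
    }
  }
  list(out = cur, cache = list(arg = arg, dims = d))
}

maxpool2d_bwd <- function(layer, cache, dout) {
  d <- cache$dims; n <- d[1L]; C <- d[4L]; s <- layer$pool
  Ho <- d[2L] %/% s; Wo <- d[3L] %/% s
  dA <- array(0, c(n, s, Ho, s, Wo, C))
  for (t2 in seq_len(s)) for (t1 in seq_len(s)) {
    code <- t1 + (t2 - 1L) * s
    tmp <- array(0, c(n, Ho, Wo, C))
    sel <- cache$arg == code
    tmp[sel] <- dout[sel]
    dA[, t1, , t2, , ] <- tmp
  }
  dx <- array(0, d)
  dx[, seq_len(Ho * s), seq_len(Wo * s), ] <- array(dA, c(n, Ho * s, Wo * s, C))
  list(dx = dx, grads = list())
}

# ---- LSTM core -------------------------------------------------------------

# Thin wrappers over the compiled time-loop kernels (src/lstm.cpp). The
# input projection is one (n*T) x F GEMM; the sequential recurrence and
# backward-through-time run in C++.
lstm_core_fwd <- function(x, Wx, Wh, b, return_sequences) {
  d <- dim(x); n <- d[1L]; Tn <- d[2L]; Fdim <- d[3L]
  X2 <- matrix(x, n * Tn, Fdim)               # row = i + (t-1)*n
  r <- lstm_fwd_cpp(X2, Wx, Wh, b, n, Tn, return_sequences)
  list(out = r$out, ptr = r$ptr, dims = d, H = ncol(Wh) / 4L)
}

lstm_core_bwd <- function(cache, dout, Wx, Wh, return_sequences) {
  d <- cache$dims; n <- d[1L]; H <- cache$H
  if (return_sequences) {
    dout_seq <- dout
    dout_last <- matrix(0, n, H)
  } else {
    dout_seq <- array(0, c(1L, 1L, 1L))       # unused placeholder
    dout_last <- matrix(dout, n, H)
  }
  r <- lstm_bwd_cpp(cache$ptr, Wx, Wh, dout_seq, dout_last, return_sequences)
  list(dx = array(r$dX2, d), dWx = r$dWx, dWh = r$dWh, db = drop(r$db))
}

reverse_time <- function(x) x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]

bilstm_fwd <- function(layer, x) {
  p <- layer$params
  fw <- lstm_core_fwd(x, p$Wx_fw, p$Wh_fw, p$b_fw, layer$return_sequences)
  bw <- lstm_core_fwd(reverse_time(x), p$Wx_bw, p$Wh_bw, p$b_bw,
                      layer$return_sequences)
  out <- if (layer$return_sequences) {
    d <- dim(fw$out)
    o <- array(0, c(d[1L], d[2L], 2L * d[3L]))
    o[, , seq_len(d[3L])] <- fw$out
    o[, , d[3L] + seq_len(d[3L])] <- reverse_time(bw$out)
    o
  } else cbind(fw$out, bw$out)
  list(out = out, cache = list(fw = fw, bw = bw))
}

bilstm_bwd <- function(layer, cache, dout) {
  p <- layer$params
  H <- cache$fw$H
  if (layer$return_sequences) {
    dfw <- dout[, , seq_len(H), drop = FALSE]
    dbw <- reverse_time(dout[, , H + seq_len(H), drop = FALSE])
  } else {
    dfw <- dout[, seq_len(H), drop = FALSE]
    dbw <- dout[, H + seq_len(H), drop = FALSE]
  }
  rf <- lstm_core_bwd(cache$fw, dfw, p$Wx_fw, p$Wh_fw, layer$return_sequences)
  rb <- lstm_core_bwd(cache$bw, dbw, p$Wx_bw, p$Wh_bw, layer$return_sequences)
  list(dx = rf$dx + reverse_time(rb$dx),
       grads = list(Wx_fw = rf$dWx, Wh_fw = rf$dWh, b_fw = rf$db,
                    Wx_bw = rb$dWx, Wh_bw = rb$dWh, b_bw = rb$db))
}

# ---- embedding / attention internals ---------------------------------------

embed_fwd <- function(layer, x) {
  if (is.matrix(x)) {
    n <- nrow(x); Tn <- ncol(x)
    X2 <- matrix(as.vector(x), n * Tn, 1L)
  } else {
    d <- dim(x); n <- d[1L]; Tn <- d[2L]
    X2 <- matrix(x, n * Tn, d[3L])
  }
  z <- sweep(X2 %*% layer$params$W, 2L, layer$params$b, "+")
  list(out = array(z, c(n, Tn, layer$d_model)),
       cache = list(X2 = X2, xdim = dim(x) %||% c(nrow(x), ncol(x)),
                    was_matrix = is.matrix(x)))
}

embed_bwd <- function(layer, cache, dout) {
  nT <- nrow(cache$X2)
  dz <- matrix(dout, nT, layer$d_model)
  dX2 <- tcrossprod(dz, layer$params$W)
  dx <- if (cache$was_matrix) {
    matrix(dX2[, 1L], cache$xdim[1L], cache$xdim[2L])
  } else array(dX2, cache$xdim)
  list(dx = dx,
       grads = list(W = crossprod(cache$X2, dz), b = colSums(dz)))
}

layernorm_core_fwd <- function(x2, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x2)
  v <- rowMeans(x2^2) - mu^2
  invstd <- 1 / sqrt(v + eps)
  xhat <- (x2 - mu) * invstd
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = y, xhat = xhat, invstd = invstd)
}

layernorm_core_bwd <- function(cache, gamma, dy) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$invstd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

layernorm_fwd <- function(params, x) {
  d <- dim(x) %||% c(1L, length(x))
  x2 <- if (is.matrix(x)) x else matrix(x, prod(d[-length(d)]), d[length(d)])
  r <- layernorm_core_fwd(x2, params$gamma, params$beta)
  out <- if (is.matrix(x)) r$y else array(r$y, d)
  list(out = out, cache = list(core = r, dims = dim(x), is_mat = is.matrix(x)))
}

layernorm_bwd <- function(params, cache, dout) {
  d2 <- if (cache$is_mat) dout else
    matrix(dout, prod(cache$dims[-length(cache$dims)]),
           cache$dims[length(cache$dims)])
  r <- layernorm_core_bwd(cache$core, params$gamma, d2)
  dx <- if (cache$is_mat) r$dx else array(r$dx, cache$dims)
  list(dx = dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

# pre-norm-free residual attention block: LN(x + dropout(MHA(x)))
mha_fwd <- function(layer, x, training) {
  p <- layer$params
  d <- dim(x); n <- d[1L]; Tn <- d[2L]; dm <- d[3L]
  h <- layer$heads; dk <- layer$key_dim
  X2 <- matrix(x, n * Tn, dm)
  Q <- sweep(X2 %*% p$Wq, 2L, p$bq, "+")
  K <- sweep(X2 %*% p$Wk, 2L, p$bk, "+")
  V <- sweep(X2 %*% p$Wv, 2L, p$bv, "+")
  Ocat <- matrix(0, n * Tn, h * dk)
  Alist <- vector("list", n * h)
  for (i in seq_len(n)) {
    idx <- i + (seq_len(Tn) - 1L) * n
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      Qh <- Q[idx, cols, drop = FALSE]
      Kh <- K[idx, cols, drop = FALSE]
      A <- softmax_rows(tcrossprod(Qh, Kh) / sqrt(dk))
      Ocat[idx, cols] <- A %*% V[idx, cols, drop = FALSE]
      Alist[[(i - 1L) * h + hh]] <- A
    }
  }
  attn <- sweep(Ocat %*% p$Wo, 2L, p$bo, "+")
  if (training && layer$dropout > 0) {
    mask <- matrix((stats::runif(length(attn)) >= layer$dropout) /
                     (1 - layer$dropout), nrow(attn), ncol(attn))
    attn_d <- attn * mask
  } else {
    mask <- NULL
    attn_d <- attn
  }
  res <- X2 + attn_d
  if (layer$layer_norm) {
    ln <- layernorm_core_fwd(res, p$gamma, p$beta)
    out2 <- ln$y
  } else {
    ln <- NULL
    out2 <- res
  }
  list(out = array(out2, d),
       cache = list(X2 = X2, Q = Q, K = K, V = V, Alist = Alist, Ocat = Ocat,
                    mask = mask, ln = ln, dims = d))
}

mha_bwd <- function(layer, cache, dout) {
  p <- layer$params
  d <- cache$dims; n <- d[1L]; Tn <- d[2L]; dm <- d[3L]
  h <- layer$heads; dk <- layer$key_dim
  dout2 <- matrix(dout, n * Tn, dm)
  if (layer$layer_norm) {
    r <- layernorm_core_bwd(cache$ln, p$gamma, dout2)
    dres <- r$dx; dgamma <- r$dgamma; dbeta <- r$dbeta
  } else {
    dres <- dout2; dgamma <- numeric(dm); dbeta <- numeric(dm)
  }
  dX2 <- dres                         # residual branch
  dattn <- if (is.null(cache$mask)) dres else dres * cache$mask
  dWo <- crossprod(cache$Ocat, dattn)
  dbo <- colSums(dattn)
  dOcat <- tcrossprod(dattn, p$Wo)
  dQ <- matrix(0, n * Tn, h * dk)
  dK <- matrix(0, n * Tn, h * dk)
  dV <- matrix(0, n * Tn, h * dk)
  for (i in seq_len(n)) {
    idx <- i + (seq_len(Tn) - 1L) * n
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      A <- cache$Alist[[(i - 1L) * h + hh]]
      Qh <- cache$Q[idx, cols, drop = FALSE]
      Kh <- cache$K[idx, cols, drop = FALSE]
      Vh <- cache$V[idx, cols, drop = FALSE]
      dO <- dOcat[idx, cols, drop = FALSE]
      dA <- tcrossprod(dO, Vh)
      dV[idx, cols] <- dV[idx, cols, drop = FALSE] + crossprod(A, dO)
      dS <- A * (dA - rowSums(dA * A))
      dQ[idx, cols] <- dQ[idx, cols, drop = FALSE] + dS %*% Kh / sqrt(dk)
      dK[idx, cols] <- dK[idx, cols, drop = FALSE] + crossprod(dS, Qh) / sqrt(dk)
    }
  }
  dX2 <- dX2 + tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  list(dx = array(dX2, d),
       grads = list(Wq = crossprod(cache$X2, dQ), bq = colSums(dQ),
                    Wk = crossprod(cache$X2, dK), bk = colSums(dK),
                    Wv = crossprod(cache$X2, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo, gamma = dgamma, beta = dbeta))
}
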