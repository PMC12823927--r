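test_that("DNN preset parameter count matches the dense-layer arithmetic", {
  m <- build_model(model_preset("dnn-paper"), 168, seed = 1)
  # closed form: sum over dense layers of (fan_in + 1) * fan_out,
  # dropout layers carry no parameters
  expected <- (168 + 1) * 231 + (231 + 1) * 77 + (77 + 1) * 22 +
    (22 + 1) * 5 + (5 + 1) * 1
  expect_equal(n_parameters(m), expected)
})

test_that("every preset yields finite outputs of the declared length", {
  n_tr <- 9L
  cases <- list(
    list("dnn-paper", "individual", 30, matrix(0, 2, 30)),
    list("cnn-real-s1", "individual", 40, array(0, c(2, 40, 1))),
    list("cnn-real-s2", "individual", 60, array(0, c(2, 60, 1))),
    list("lstm-paper", "individual", 15, array(0, c(2, 15, 1))),
    list("bilstm-paper", "individual", 15, array(0, c(2, 15, 1))),
    list("transformer-paper", "individual", 18, matrix(0, 2, 18)),
    list("dnn-paper", "summary", 55, matrix(0, 1, 55)),
    list("cnn-real-s1-2d", "summary", c(12, 12), array(0, c(3, 12, 12, 1))),
    list("lstm-paper", "summary", c(8, 8), array(0, c(1, 8, 8))),
    list("bilstm-paper", "summary", c(8, 8), array(0, c(1, 8, 8))),
    list("transformer-paper", "summary", c(4, 25), array(0, c(1, 4, 25))))
  for (cs in cases) {
    spec <- if (cs[[2]] == "summary") {
      model_preset(cs[[1]], input_mode = "summary", n_train = n_tr,
                   window = 10, stride = 5)
    } else model_preset(cs[[1]], window = 10, stride = 5)
    m <- build_model(spec, cs[[3]], seed = 4)
    out <- ldrisk:::model_forward(m, cs[[4]], training = FALSE)$out
    expect_true(all(is.finite(out)), info = cs[[1]])
    expect_equal(ncol(out), spec$output_dim, info = cs[[1]])
    # final layer is linear by construction
    last <- m$layers[[length(m$layers)]]
    expect_identical(last$activation, "linear", info = cs[[1]])
  }
})

test_that("builds and evaluation passes are deterministic; dropout only acts in training", {
  spec <- model_preset("dnn-paper")
  m1 <- build_model(spec, 25, seed = 7)
  m2 <- build_model(spec, 25, seed = 7)
  probe <- matrix(seq_len(50) / 50, 2, 25)
  o1 <- ldrisk:::model_forward(m1, probe, training = FALSE)$out
  o2 <- ldrisk:::model_forward(m2, probe, training = FALSE)$out
  expect_identical(o1, o2)
  # two evaluation passes agree exactly (dropout disabled at inference)
  expect_identical(o1, ldrisk:::model_forward(m1, probe, FALSE)$out)
  # a different seed gives different weights
  m3 <- build_model(spec, 25, seed = 8)
  expect_false(identical(o1, ldrisk:::model_forward(m3, probe, FALSE)$out))
})

test_that("summary models emit one output per training sample from an LD input", {
  pan <- make_panel(n = 60, p = 24, seed = 10)
  n_tr <- length(pan$sp$train_indices)
  ld <- compute_ld(pan$Gstd, pan$sp$train_indices)
  spec <- model_preset("dnn-paper", input_mode = "summary", n_train = n_tr)
  m <- build_model(spec, length(upper_triangle(ld)), seed = 1)
  expect_length(predict(m, ld), n_tr)
  # individual mode: one prediction per row
  spec_i <- model_preset("dnn-paper")
  mi <- build_model(spec_i, 24, seed = 1)
  expect_length(predict(mi, pan$Gstd$values[1:5, ]), 5)
})

test_that("block-set summary models accept any number of blocks without rebuild", {
  pan <- make_panel(n = 60, p = 24, seed = 11)
  ld <- compute_ld(pan$Gstd)
  spec <- model_preset("cnn-real-s1-2d", input_mode = "summary", n_train = 8)
  m <- build_model(spec, c(12, 12), seed = 2)
  out3 <- predict(m, partition_blocks(ld, 12))          # 2 blocks
  # a finer partition of a wider panel: same block size, more blocks
  pan2 <- make_panel(n = 60, p = 36, seed = 12)
  out4 <- predict(m, partition_blocks(compute_ld(pan2$Gstd), 12))  # 3 blocks
  expect_length(out3, 8)
  expect_length(out4, 8)
  # transformer summary: tokens are flattened blocks
  st <- model_preset("transformer-paper", input_mode = "summary", n_train = 8)
  mt <- build_model(st, c(2, 144), seed = 2)
  expect_length(predict(mt, partition_blocks(ld, 12)), 8)
  expect_length(predict(mt, partition_blocks(compute_ld(pan2$Gstd), 12)), 8)
})
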