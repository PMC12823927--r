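test_that("mse_loss matches hand values and its algebraic identities", {
  expect_equal(mse_loss(c(1, 2), c(0, 0)), 2.5)
  expect_equal(mse_loss(1:5, 1:5), 0)
  set.seed(1)
  o <- rnorm(40); y <- rnorm(40)
  expect_equal(mse_loss(o + 3, y + 3), mse_loss(o, y), tolerance = 1e-12)
  # mse = Var_pop(O - Y) + mean(O - Y)^2
  expect_equal(mse_loss(o, y), var_pop(o - y) + mean(o - y)^2,
               tolerance = 1e-12)
  expect_error(mse_loss(1:3, 1:4), "equal length")
})

test_that("the learning-rate schedule is exponential per epoch", {
  tc <- train_config(initial_lr = 0.001, decay_rate = 0.96)
  expect_equal(lr_at_epoch(tc, 0), 0.001)
  expect_equal(lr_at_epoch(tc, 1), 0.00096)
  tc1 <- train_config(decay_rate = 1)
  expect_equal(lr_at_epoch(tc1, 0:9), rep(tc1$initial_lr, 10))
  # the 100-epoch schedule is a geometric sequence of ratio 0.96
  dnn <- train_preset("dnn-paper")
  lrs <- lr_at_epoch(dnn, 0:(dnn$epochs - 1))
  expect_length(lrs, 100)
  expect_equal(unique(round(lrs[-1] / lrs[-100], 10)), 0.96)
})

test_that("individual-mode fitting solves a realizable linear regression", {
  set.seed(5)
  X <- matrix(rnorm(200 * 10), 200)
  y <- drop(X %*% rnorm(10))
  spec <- architecture_spec("dnn", "individual",
                            list(layer_dense(16L, "relu")), 1L)
  m <- build_model(spec, 10, seed = 1)
  tc <- train_config(epochs = 500, batch_size = 64, initial_lr = 0.01,
                     decay_rate = 1, seed = 1)
  fit <- fit_individual(m, X, y, tc)
  expect_lt(fit$final_train_error, 1e-3)
  expect_length(fit$loss_history, 500)
  # loss trends downward
  expect_lt(mean(tail(fit$loss_history, 5)), mean(head(fit$loss_history, 5)))
  # bit-reproducible
  fit2 <- fit_individual(build_model(spec, 10, seed = 1), X, y, tc)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_equal(fit$final_train_error, fit2$final_train_error)
})

test_that("summary-mode fitting memorizes the training responses", {
  pan <- make_panel(n = 80, p = 40, seed = 2)
  ld <- compute_ld(pan$Gstd)
  set.seed(3)
  y <- rnorm(50)
  spec <- model_preset("dnn-paper", input_mode = "summary", n_train = 50)
  m <- build_model(spec, length(upper_triangle(ld)), seed = 1)
  tc <- train_config(epochs = 400, batch_size = 256, initial_lr = 0.005,
                     decay_rate = 1, seed = 1)
  fit <- fit_summary(m, ld, y, tc)
  # the single-example target is memorizable with enough capacity
  expect_lt(fit$final_train_error, 0.05 * var_pop(y))
  expect_length(fit$loss_history, 400)
  # constant target: reachable to near zero (bias alone suffices; ADAM
  # steps are bounded by the learning rate, so give it room to travel)
  yc <- rep(2.5, 50)
  tc_c <- train_config(epochs = 400, batch_size = 256, initial_lr = 0.02,
                       decay_rate = 1, seed = 1)
  fitc <- fit_summary(build_model(spec, length(upper_triangle(ld)), seed = 1),
                      ld, yc, tc_c)
  expect_lt(fitc$final_train_error, 1e-3)
  # determinism
  fit2 <- fit_summary(build_model(spec, length(upper_triangle(ld)), seed = 1),
                      ld, y, tc)
  expect_identical(fit$loss_history, fit2$loss_history)
  # mismatched output dimension is rejected
  expect_error(fit_summary(m, ld, rnorm(20), tc), "output_dim")
})

test_that("summary fitting never sees test data by construction", {
  expect_false(any(grepl("test", names(formals(fit_summary)))))
})
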