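test_that("individual test error composes predict with mse_loss", {
  pan <- make_panel(n = 60, p = 20, seed = 17)
  m <- build_model(model_preset("dnn-paper"), 20, seed = 3)
  x_te <- pan$Gstd$values[pan$sp$test_indices, , drop = FALSE]
  y_te <- pan$ph$values[pan$sp$test_indices]
  expect_equal(test_error_individual(m, x_te, y_te),
               mse_loss(predict(m, x_te), y_te), tolerance = 1e-12)
  # perfect and constant predictors via the loss identity
  expect_equal(mse_loss(y_te, y_te), 0)
  expect_equal(mse_loss(rep(1.5, length(y_te)), y_te),
               var_pop(y_te) + (1.5 - mean(y_te))^2, tolerance = 1e-12)
})

test_that("the all-pairs oracle equals brute force and its variance decomposition", {
  # brute force over both pairs: O = (0, 2), y = 1 -> 1
  expect_equal(allpairs_oracle(c(0, 2), 1), 1)
  expect_equal(allpairs_oracle(c(3, 3), c(3, 3, 3)), 0)
  set.seed(4)
  o <- rnorm(37); y <- rnorm(11)
  brute <- mean(outer(o, y, "-")^2)
  expect_equal(allpairs_oracle(o, y), brute, tolerance = 1e-12)
  expect_equal(allpairs_oracle(o, y),
               var_pop(o) + var_pop(y) + (mean(o) - mean(y))^2,
               tolerance = 1e-12)
})

test_that("bootstrap test error is exact in degenerate cases and deterministic", {
  y <- c(1, 2, 4)
  # constant outputs: every resample gives the same error, for any B/seed
  b <- bootstrap_test_error(rep(2, 10), y, B = 50, seed = 3)
  expect_equal(b$te_hat, mean((2 - y)^2), tolerance = 1e-12)
  expect_equal(b$mc_se, 0)
  # single output atom
  b1 <- bootstrap_test_error(5, y, B = 25, seed = 9)
  expect_equal(b1$te_hat, mean((5 - y)^2), tolerance = 1e-12)
  # invariants and determinism
  set.seed(8)
  o <- rnorm(30); yy <- rnorm(12)
  b2 <- bootstrap_test_error(o, yy, B = 400, seed = 5)
  expect_equal(b2$te_hat, mean(b2$resample_errors), tolerance = 1e-12)
  expect_equal(b2$B, 400L)
  b3 <- bootstrap_test_error(o, yy, B = 400, seed = 5)
  expect_identical(b2$resample_errors, b3$resample_errors)
  expect_error(bootstrap_test_error(numeric(0), yy), "non-empty")
})

test_that("the bootstrap mean is unbiased for the all-pairs limit", {
  set.seed(6)
  o <- rnorm(25); y <- rnorm(10)
  truth <- allpairs_oracle(o, y)
  ests <- vapply(1:50, function(s) {
    bootstrap_test_error(o, y, B = 200, seed = s)$te_hat
  }, numeric(1))
  se <- sd(ests) / sqrt(50)
  expect_lt(abs(mean(ests) - truth), 4 * se)
})

test_that("Monte-Carlo error shrinks as 1/sqrt(B)", {
  set.seed(7)
  o <- rnorm(200); y <- rnorm(50)
  ses <- vapply(c(100, 400, 1600), function(B) {
    bootstrap_test_error(o, y, B = B, seed = 11)$mc_se
  }, numeric(1))
  # each 4x increase in B should halve mc_se, within a factor of 2
  expect_lt(ses[2] / ses[1], 1)
  expect_lt(ses[3] / ses[2], 1)
  expect_gt(ses[1] / ses[3], 4 / 2)
  expect_lt(ses[1] / ses[3], 4 * 2)
})

test_that("the replicate harness reports reproducible mean/sd cells", {
  cfg <- simulation_config(n_individuals = 60, n_snps = 30, seed = 19)
  tc <- list("dnn-paper" = train_config(epochs = 5, batch_size = 32,
                                        initial_lr = 0.002, seed = 1))
  rep1 <- replicate_experiment(cfg, methods = "dnn-paper",
                               modes = c("individual", "summary"),
                               R = 2, B = 200, train_configs = tc, seed = 5)
  rep2 <- replicate_experiment(cfg, methods = "dnn-paper",
                               modes = c("individual", "summary"),
                               R = 2, B = 200, train_configs = tc, seed = 5)
  expect_identical(rep1, rep2)
  expect_setequal(rep1$mode, c("individual", "summary"))
  expect_true(all(is.finite(rep1$train_mean)))
  det <- attr(rep1, "details")
  expect_equal(nrow(det), 4)
  # summary-mode test error of a barely trained model obeys the oracle
  # identity scale: close to Var(O) + Var(y) + mean-difference term, hence
  # at least Var_pop(y_test) in this near-constant-output regime
  sm <- det[det$mode == "summary", ]
  expect_gt(min(sm$test_error / sm$var_y_test), 0.5)
})
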