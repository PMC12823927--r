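test_that("BLUP equals the ridge closed form (Woodbury identity)", {
  set.seed(21)
  for (r in 1:5) {
    n <- 25; p <- 40
    Z <- matrix(rnorm(n * p), n) / sqrt(p)
    y <- rnorm(n)
    lam <- runif(1, 0.2, 5)
    vc <- structure(list(sigma_u2 = 1, sigma_e2 = lam),
                    class = "variance_components")
    Zte <- matrix(rnorm(10 * p), 10) / sqrt(p)
    got <- blup_predict(Z, y, Zte, vc)
    # primal ridge: (Z'Z + lam I)^-1 Z' (y - ybar)
    beta <- solve(crossprod(Z) + diag(lam, p), crossprod(Z, y - mean(y)))
    expect_equal(got, drop(mean(y) + Zte %*% beta), tolerance = 1e-8)
  }
})

test_that("a 3-sample 2-SNP toy matches explicit matrix inversion", {
  Z <- matrix(c(1, 0, -1,
                0.5, -0.5, 0), 3)
  y <- c(2, 1, 0)
  vc <- structure(list(sigma_u2 = 1, sigma_e2 = 1),
                  class = "variance_components")
  # by hand: u = Z'(ZZ' + I)^-1 (y - 1), predictions = 1 + Z u
  yc <- y - 1
  u <- crossprod(Z, solve(tcrossprod(Z) + diag(3), yc))
  expect_equal(blup_predict(Z, y, Z, vc), drop(1 + Z %*% u),
               tolerance = 1e-12)
})

test_that("lambda -> 0 interpolates training data; sigma_u2 = 0 predicts the mean", {
  set.seed(22)
  n <- 10; p <- 30
  Z <- matrix(rnorm(n * p), n)
  y <- rnorm(n)
  vc0 <- structure(list(sigma_u2 = 1, sigma_e2 = 1e-10),
                   class = "variance_components")
  expect_equal(blup_predict(Z, y, Z, vc0), y, tolerance = 1e-5)
  vcn <- structure(list(sigma_u2 = 0, sigma_e2 = 1),
                   class = "variance_components")
  expect_equal(blup_predict(Z, y, Z, vcn), rep(mean(y), n))
})

test_that("REML recovers variance components and detects null signal", {
  set.seed(23)
  reps <- 20; n <- 200; p <- 80
  est <- matrix(0, reps, 2)
  for (r in 1:reps) {
    Z <- matrix(rnorm(n * p), n) / sqrt(p)
    u <- rnorm(p, 0, sqrt(1.0))
    y <- drop(Z %*% u) + rnorm(n, 0, sqrt(0.8))
    vc <- estimate_variance_components(Z, y)
    # the per-effect scale: Var(Zu) ~ sigma_u2 * rowSums(Z^2) ~ sigma_u2
    est[r, ] <- c(vc$sigma_u2, vc$sigma_e2)
  }
  expect_lt(abs(mean(est[, 1]) - 1.0) / 1.0, 0.2)
  expect_lt(abs(mean(est[, 2]) - 0.8) / 0.8, 0.2)
  # pure noise: genetic variance estimated near zero
  Z <- matrix(rnorm(n * p), n) / sqrt(p)
  y <- rnorm(n)
  vc0 <- estimate_variance_components(Z, y)
  expect_lt(vc0$sigma_u2, 0.15)
  # deterministic given fixed data
  expect_identical(estimate_variance_components(Z, y),
                   estimate_variance_components(Z, y))
})

test_that("BLUP beats the constant-mean predictor on the linear design", {
  # the win frequency depends on the test-set size averaging the per-split
  # MSE noise, so this runs at the design's sample size (n = 1092,
  # n_te = 219) with the SNP count reduced for runtime
  set.seed(24)
  wins <- 0
  for (r in 1:50) {
    cfg <- simulation_config(n_individuals = 1092, n_snps = 300,
                             maf_range = c(0.1, 0.45), seed = 300 + r)
    Gstd <- standardize_genotypes(simulate_genotypes(cfg))
    ph <- simulate_phenotype(Gstd, cfg)
    sp <- split_data(1092, 0.8, seed = 300 + r)
    Ztr <- Gstd$values[sp$train_indices, , drop = FALSE]
    Zte <- Gstd$values[sp$test_indices, , drop = FALSE]
    ytr <- ph$values[sp$train_indices]
    yte <- ph$values[sp$test_indices]
    pred <- blup_predict(Ztr, ytr, Zte)
    blup_mse <- mse_loss(pred, yte)
    const_mse <- mse_loss(rep(mean(ytr), length(yte)), yte)
    wins <- wins + (blup_mse < const_mse)
  }
  expect_gte(wins, 45)
})
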