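test_that("simulated genotypes have the requested MAF spectrum and are reproducible", {
  cfg <- simulation_config(n_individuals = 10000, n_snps = 60,
                           maf_range = c(0.05, 0.45), block_length = 5,
                           within_block_corr = 0, seed = 11)
  G <- simulate_genotypes(cfg)
  expect_true(all(G$values %in% 0:2))
  # under independence each SNP's sample frequency is within 3 binomial sd
  # of its target; recover targets from the seeded draw
  set.seed(11)
  maf <- runif(60, 0.05, 0.45)
  freq <- colMeans(G$values) / 2
  sd3 <- 3 * sqrt(maf * (1 - maf) / (2 * 10000))
  expect_true(all(abs(freq - maf) < sd3 + 1e-12))
  # independence: pairwise dosage correlations centred at zero
  cc <- cor(G$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  # determinism
  expect_identical(G$values, simulate_genotypes(cfg)$values)
})

test_that("within-block LD exceeds between-block LD under block correlation", {
  cfg <- simulation_config(n_individuals = 10000, n_snps = 100,
                           block_length = 5, within_block_corr = 0.9,
                           maf_range = c(0.1, 0.4), seed = 12)
  G <- simulate_genotypes(cfg)
  cc <- abs(cor(G$values))
  blk <- rep(seq_len(20), each = 5)
  same <- outer(blk, blk, "==") & upper.tri(cc)
  diff <- (!outer(blk, blk, "==")) & upper.tri(cc)
  expect_gt(mean(cc[same]), 5 * mean(cc[diff]))
})

test_that("MAF filtering keeps exactly the SNPs at or above threshold, in order", {
  # sample MAFs {0, 0.001, 0.01, 0.4} by construction (n = 1000)
  vals <- cbind(rep(0L, 1000),
                c(rep(1L, 2), rep(0L, 998)),
                c(rep(1L, 20), rep(0L, 980)),
                c(rep(1L, 800), rep(0L, 200)))
  G <- toy_genotypes(vals)
  expect_equal(G$mafs, c(0, 0.001, 0.01, 0.4))
  kept <- filter_maf(G, 0.001)
  expect_equal(kept$snp_ids, c("s2", "s3", "s4"))
  expect_equal(ncol(filter_maf(G, 0)$values), 4L)
  expect_error(filter_maf(G, 0.45), "no SNPs")
})

test_that("standardization gives mean 0, sd 1/sqrt(p), and exact round-trip", {
  pan <- make_panel(n = 80, p = 25, seed = 3)
  v <- pan$Gstd$values
  p <- ncol(v)
  expect_lt(max(abs(colMeans(v))), 1e-10)
  sds <- sqrt(colMeans(v^2))
  expect_lt(max(abs(sds - 1 / sqrt(p))), 1e-8)
  expect_equal(unstandardize_genotypes(pan$Gstd), pan$G$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  # p = 1: output column sd is 1
  g1 <- toy_genotypes(matrix(c(0L, 1L, 2L, 1L), 4))
  s1 <- standardize_genotypes(g1)
  expect_equal(sqrt(mean(s1$values^2)), 1, tolerance = 1e-12)
  # 2 x 2 hand case under the population-sd convention: means 1, sds 1,
  # scaling by sqrt(2) gives +-(1/2)/sqrt(2) ... i.e. +-1/sqrt(2)
  g2 <- toy_genotypes(matrix(c(0L, 2L, 2L, 0L), 2))
  s2 <- standardize_genotypes(g2)
  expect_equal(s2$values,
               matrix(c(-1, 1, 1, -1) / sqrt(2), 2), tolerance = 1e-12)
  # constant column errors and names the SNP
  expect_error(standardize_genotypes(toy_genotypes(cbind(c(0L, 1L), c(1L, 1L)))),
               "s2")
})

test_that("phenotype follows the linear polygenic model", {
  pan <- make_panel(n = 60, p = 20, seed = 5)
  expect_length(pan$ph$values, 60)
  expect_length(pan$ph$causal_indices, round(0.3 * 20))
  # variance identity given the drawn weights: Var(Y) differs from
  # w' Sigma_causal w + noise_sd^2 only through the realized eps
  big <- make_panel(n = 800, p = 40, seed = 15)
  Zc <- big$Gstd$values[, big$ph$causal_indices, drop = FALSE]
  gen <- drop(Zc %*% big$ph$weights)
  eps <- big$ph$values - gen
  model_var <- drop(crossprod(big$ph$weights,
                              (crossprod(Zc) / 800) %*% big$ph$weights)) + 1
  # eps sample variance has sd ~ sqrt(2/n); allow 4 of those plus the
  # gen-eps cross term of similar order
  expect_lt(abs(var_pop(big$ph$values) - model_var), 8 * sqrt(2 / 800))
  # noiseless, fully causal, zero effects -> Var(Y) = noise variance
  cfg0 <- simulation_config(n_individuals = 400, n_snps = 10,
                            causal_fraction = 1, w_sd = 0, noise_sd = 1,
                            seed = 8)
  G0 <- standardize_genotypes(simulate_genotypes(cfg0))
  y0 <- simulate_phenotype(G0, cfg0)
  expect_lt(abs(var(y0$values) - 1), 0.25)
  # noiseless single-SNP: Y equals w_1 times the causal column exactly
  cfg1 <- simulation_config(n_individuals = 50, n_snps = 3,
                            causal_fraction = 1 / 3, noise_sd = 0, seed = 9)
  G1 <- standardize_genotypes(simulate_genotypes(cfg1))
  y1 <- simulate_phenotype(G1, cfg1)
  expect_equal(y1$values,
               drop(G1$values[, y1$causal_indices] * y1$weights),
               tolerance = 1e-12)
})

test_that("phenotype variance matches the law-of-total-variance prediction", {
  # independent SNPs, defaults: Var(Y) -> 1 + K * 0.36 / p over redraws
  p <- 200; n <- 400
  cfg <- simulation_config(n_individuals = n, n_snps = p,
                           within_block_corr = 0, seed = 21)
  Gstd <- standardize_genotypes(simulate_genotypes(cfg))
  vars <- vapply(1:30, function(r) {
    cfg_r <- cfg; cfg_r$seed <- 21 + r
    var_pop(simulate_phenotype(Gstd, cfg_r)$values)
  }, numeric(1))
  K <- round(0.3 * p)
  expect_equal(mean(vars), 1 + K * 0.36 / p, tolerance = 0.05)
})

test_that("splits have floor(train_fraction * n) training samples and are disjoint", {
  s <- split_data(1092, 0.8, seed = 1)
  expect_length(s$train_indices, 873)
  expect_length(s$test_indices, 219)
  expect_length(intersect(s$train_indices, s$test_indices), 0)
  expect_setequal(c(s$train_indices, s$test_indices), 1:1092)
  expect_equal(lengths(split_data(10, 0.5, 2)[c(1, 2)]),
               c(train_indices = 5L, test_indices = 5L))
  expect_identical(split_data(100, 0.8, 42), split_data(100, 0.8, 42))
  expect_error(split_data(5, 0.1), "empty")
})
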