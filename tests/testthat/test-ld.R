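test_that("compute_ld is the scaled Gram matrix with the right structure", {
  # hand case: rows (1,0) and (0,-1) -> (1/2) I
  Gstd <- structure(list(values = matrix(c(1, 0, 0, -1), 2),
                         snp_ids = c("a", "b"), sample_ids = c("x", "y")),
                    class = "std_genotypes")
  ld <- compute_ld(Gstd)
  expect_equal(ld$values, diag(0.5, 2), tolerance = 1e-12)
  expect_equal(ld$n_source, 2L)

  pan <- make_panel(n = 100, p = 30, seed = 2)
  ld <- compute_ld(pan$Gstd)
  # symmetric, PSD, diagonal equals the column mean squares
  expect_lt(max(abs(ld$values - t(ld$values))), 1e-10)
  ev <- eigen(ld$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  expect_equal(diag(ld$values), colMeans(pan$Gstd$values^2), tolerance = 1e-12)
  # two identical columns give off-diagonal equal to the diagonals
  v2 <- cbind(pan$Gstd$values[, 1], pan$Gstd$values[, 1])
  Gd <- structure(list(values = v2, snp_ids = c("a", "b"),
                       sample_ids = pan$Gstd$sample_ids),
                  class = "std_genotypes")
  ld2 <- compute_ld(Gd)
  expect_equal(ld2$values[1, 2], ld2$values[1, 1], tolerance = 1e-12)
  expect_error(compute_ld(pan$Gstd, integer(0)), "non-empty")
})

test_that("full-sample LD is the split-size weighted average of train/test LD", {
  pan <- make_panel(n = 90, p = 20, seed = 4)
  n_tr <- length(pan$sp$train_indices)
  n_te <- length(pan$sp$test_indices)
  full <- compute_ld(pan$Gstd)$values
  tr <- compute_ld(pan$Gstd, pan$sp$train_indices)$values
  te <- compute_ld(pan$Gstd, pan$sp$test_indices)$values
  expect_equal(full, (n_tr * tr + n_te * te) / 90, tolerance = 1e-12)
})

test_that("diagonal-block partition counts, padding and reassembly are exact", {
  expect_equal(nrow(block_plan(8299, 193)), 43L)
  expect_false(any(block_plan(8299, 193)$padded))

  pan <- make_panel(n = 60, p = 10, seed = 6)
  ld <- compute_ld(pan$Gstd)
  # p = 10, block 3 -> ceiling(10/3) = 4 blocks, last padded from 1x1
  bs <- partition_blocks(ld, 3)
  expect_equal(bs$n_blocks, 4L)
  expect_true(bs$padded)
  expect_equal(dim(bs$blocks[[4]]), c(3L, 3L))
  expect_equal(bs$blocks[[4]][1, 1], ld$values[10, 10])
  expect_equal(bs$blocks[[4]][2:3, ], matrix(0, 2, 3))
  # reassembling the diagonal band reproduces it exactly
  for (k in 1:3) {
    idx <- bs$index_ranges$start[k]:bs$index_ranges$end[k]
    expect_equal(bs$blocks[[k]], ld$values[idx, idx], tolerance = 1e-15)
  }
  # single block equal to the input
  one <- partition_blocks(ld, 10)
  expect_equal(one$n_blocks, 1L)
  expect_equal(one$blocks[[1]], ld$values)
  expect_error(partition_blocks(ld, 11), "exceeds")
})

test_that("upper-triangle vectorization is a bijection with known lengths", {
  m <- matrix(c(1, 2, 2, 3), 2)
  expect_length(upper_triangle(m), 3)
  expect_equal(upper_triangle(m), c(1, 2, 3))      # row-major upper
  expect_length(upper_triangle(m, include_diagonal = FALSE), 1)
  expect_equal(168 * 169 / 2, 14196)
  pan <- make_panel(n = 50, p = 168, seed = 13)
  ld <- compute_ld(pan$Gstd)
  v <- upper_triangle(ld)
  expect_length(v, 14196)
  expect_equal(ld_from_upper_triangle(v, 168), ld$values, tolerance = 1e-15)
})

test_that("sliding windows cover the sequence as specified", {
  w <- window_slices(8299, 1000, 500, strict_paper = TRUE)
  expect_equal(nrow(w), 15L)
  expect_equal(w$start, seq(1, 7001, by = 500))
  expect_false(any(w$partial))
  # default appends a flagged trailing window reaching the last SNP
  w2 <- window_slices(8299, 1000, 500)
  expect_equal(nrow(w2), 16L)
  expect_true(w2$partial[16])
  expect_equal(w2$end[16], 8299L)
  # exact-fit cases
  expect_equal(nrow(window_slices(1000, 1000, 500)), 1L)
  w3 <- window_slices(1500, 1000, 500)
  expect_equal(nrow(w3), 2L)
  expect_false(any(w3$partial))
  expect_error(window_slices(10, 20, 5), "exceeds")
})
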