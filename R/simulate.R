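#' Simulation settings for the synthetic SNP panel
#'
#' Bundles every parameter of the genotype/phenotype generator. The defaults
#' reproduce the study design used throughout the package's simulation
#' experiments: a 1 Mb-style panel of `n_snps` common SNPs with minor allele
#' frequencies drawn uniformly from `maf_range`, haplotype-block LD, and a
#' linear polygenic trait in which 30% of SNPs are causal with
#' N(0, 0.6^2) effects on the standardized scale plus N(0, 1) noise.
#'
#' @param n_individuals Number of individuals `n`.
#' @param n_snps Number of SNPs `p`.
#' @param maf_range Length-2 numeric, lower/upper bound of the per-SNP minor
#'   allele frequency, both in (0, 0.5).
#' @param block_length Number of consecutive SNPs per haplotype block.
#' @param within_block_corr Latent-Gaussian correlation shared by SNPs in the
#'   same block, in \[0, 1). 0 gives independent SNPs.
#' @param causal_fraction Fraction of SNPs assigned a nonzero effect.
#' @param w_sd Standard deviation of the causal effect sizes `w_k`.
#' @param noise_sd Standard deviation of the residual noise.
#' @param train_fraction Fraction of samples assigned to the training set.
#' @param seed Integer seed; all generators are bit-reproducible given it.
#'
#' @return A `simulation_config` list.
#' @examples
#' cfg <- simulation_config(n_individuals = 200, n_snps = 100, seed = 1)
#' @export
simulation_config <- function(n_individuals = 1092L,
                              n_snps = 8299L,
                              maf_range = c(0.001, 0.5),
                              block_length = 20L,
                              within_block_corr = 0.7,
                              causal_fraction = 0.3,
                              w_sd = 0.6,
                              noise_sd = 1,
                              train_fraction = 0.8,
                              seed = 1L) {
  cfg <- list(
    n_individuals = assert_count(n_individuals, "n_individuals"),
    n_snps = assert_count(n_snps, "n_snps"),
    maf_range = maf_range,
    block_length = assert_count(block_length, "block_length"),
    within_block_corr = assert_number(within_block_corr, "within_block_corr",
                                      0, 1, strict_upper = TRUE),
    causal_fraction = assert_number(causal_fraction, "causal_fraction",
                                    0, 1, strict_lower = TRUE),
    w_sd = assert_number(w_sd, "w_sd", 0),
    noise_sd = assert_number(noise_sd, "noise_sd", 0),
    train_fraction = assert_number(train_fraction, "train_fraction", 0, 1,
                                   strict_lower = TRUE, strict_upper = TRUE),
    seed = assert_count(seed, "seed", min = 0L)
  )
  # the upper bound is exclusive (frequencies are drawn in [lower, upper)),
  # so upper = 0.5 is allowed and never attained
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      !(0 < maf_range[1] && maf_range[1] <= maf_range[2] && maf_range[2] <= 0.5)) {
    stop_ldrisk("`maf_range` must satisfy 0 < lower <= upper <= 0.5 (upper exclusive in draws)")
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: n=%d, p=%d, MAF in [%g, %g), blocks of %d (rho=%g)\n",
    x$n_individuals, x$n_snps, x$maf_range[1], x$maf_range[2],
    x$block_length, x$within_block_corr))
  cat(sprintf("  trait: %g causal, w ~ N(0, %g^2), noise sd %g; train fraction %g; seed %d\n",
              x$causal_fraction, x$w_sd, x$noise_sd, x$train_fraction, x$seed))
  invisible(x)
}

new_genotype_matrix <- function(values, snp_ids, sample_ids) {
  freq <- colMeans(values) / 2
  structure(list(values = values,
                 snp_ids = snp_ids,
                 sample_ids = sample_ids,
                 mafs = pmin(freq, 1 - freq)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs, sample MAF in [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$mafs), max(x$mafs)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Simulate additive genotype dosages with haplotype-block LD
#'
#' Draws a panel of `n` individuals by `p` SNPs in additive 0/1/2 coding from
#' a latent-Gaussian threshold model. Each haplotype allele at SNP `k` is the
#' indicator that a standard-normal latent variable falls below the MAF
#' quantile, so dosages are Binomial(2, maf_k) marginally; latent variables
#' of SNPs in the same block of `block_length` consecutive SNPs share a
#' common factor giving pairwise correlation `within_block_corr`, while
#' blocks are independent. This reproduces the two properties downstream
#' stages rely on -- a controllable MAF spectrum and local LD -- without any
#' external reference panel.
#'
#' @param config A [simulation_config()].
#' @return A `genotype_matrix` with fields `values` (n x p integer dosages),
#'   `snp_ids`, `sample_ids`, and `mafs` (sample minor allele frequencies).
#' @examples
#' G <- simulate_genotypes(simulation_config(n_individuals = 50, n_snps = 40,
#'                                           seed = 7))
#' table(G$values)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_individuals
  p <- config$n_snps
  rho <- config$within_block_corr
  set.seed(config$seed)

  maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(maf)
  block <- rep(seq_len(ceiling(p / config$block_length)),
               each = config$block_length)[seq_len(p)]
  n_blocks <- max(block)

  dosage <- matrix(0L, n, p)
  for (h in 1:2) {
    shared <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    z <- sqrt(rho) * shared[, block, drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
    dosage <- dosage + (z < matrix(thr, n, p, byrow = TRUE))
  }
  storage.mode(dosage) <- "integer"
  new_genotype_matrix(dosage,
                      snp_ids = sprintf("snp%05d", seq_len(p)),
                      sample_ids = sprintf("ind%05d", seq_len(n)))
}

#' Remove SNPs below a minor-allele-frequency threshold
#'
#' Retains exactly the SNPs whose sample MAF is at least `threshold`,
#' preserving order. Rare variants weaken the signal available to the
#' prediction models, so panels are filtered (default threshold 0.001)
#' before standardization.
#'
#' @param G A `genotype_matrix`.
#' @param threshold MAF threshold in \[0, 0.5).
#' @return A filtered `genotype_matrix`.
#' @export
filter_maf <- function(G, threshold = 0.001) {
  stopifnot(inherits(G, "genotype_matrix"))
  threshold <- assert_number(threshold, "threshold", 0, 0.5, strict_upper = TRUE)
  keep <- G$mafs >= threshold
  if (!any(keep)) stop_ldrisk("no SNPs pass the MAF threshold")
  new_genotype_matrix(G$values[, keep, drop = FALSE],
                      snp_ids = G$snp_ids[keep],
                      sample_ids = G$sample_ids)
}

#' Standardize genotype columns to mean 0, sd 1/sqrt(p)
#'
#' Transforms each dosage column as `(x - m) / (s * sqrt(p))` where `m` and
#' `s` are the column mean and standard deviation and `p` the number of SNPs,
#' so that the LD matrix `(1/n) G'G` of the result has unit trace scale. The
#' population sd convention (divide by n) is the default: it makes each
#' diagonal entry of the full-sample LD matrix exactly `1/p`. The original
#' `m` and `s` are stored so the dosages can be recovered exactly.
#'
#' @param G A `genotype_matrix`.
#' @param sd_method `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @return A `std_genotypes` object with fields `values`, `snp_ids`,
#'   `sample_ids`, `column_means`, `column_sds`.
#' @export
standardize_genotypes <- function(G, sd_method = c("population", "sample")) {
  stopifnot(inherits(G, "genotype_matrix"))
  sd_method <- match.arg(sd_method)
  x <- G$values
  p <- ncol(x)
  m <- colMeans(x)
  s <- col_sds(x, sd_method)
  if (any(s == 0)) {
    stop_ldrisk("constant genotype column(s): ",
                paste(G$snp_ids[s == 0], collapse = ", "))
  }
  vals <- sweep(sweep(x, 2L, m, "-"), 2L, s * sqrt(p), "/")
  structure(list(values = vals,
                 snp_ids = G$snp_ids,
                 sample_ids = G$sample_ids,
                 column_means = m,
                 column_sds = s,
                 sd_method = sd_method),
            class = "std_genotypes")
}

#' @export
print.std_genotypes <- function(x, ...) {
  cat(sprintf("std_genotypes: %d x %d, columns mean 0, sd 1/sqrt(%d) (%s sd)\n",
              nrow(x$values), ncol(x$values), ncol(x$values), x$sd_method))
  invisible(x)
}

#' @export
dim.std_genotypes <- function(x) dim(x$values)

#' Recover raw dosages from standardized genotypes
#'
#' Inverts [standardize_genotypes()] using the stored column means and sds.
#'
#' @param Gstd A `std_genotypes` object.
#' @return The n x p numeric dosage matrix.
#' @export
unstandardize_genotypes <- function(Gstd) {
  stopifnot(inherits(Gstd, "std_genotypes"))
  p <- ncol(Gstd$values)
  sweep(sweep(Gstd$values, 2L, Gstd$column_sds * sqrt(p), "*"),
        2L, Gstd$column_means, "+")
}

#' Simulate a linear polygenic quantitative trait
#'
#' Draws `K = round(causal_fraction * p)` causal SNPs without replacement,
#' effects `w_k ~ N(0, w_sd^2)` and noise `e_i ~ N(0, noise_sd^2)`, and
#' returns `Y_i = sum_k w_k g_ik + e_i` on the standardized genotype scale.
#' Uses a seed stream offset from the genotype seed so effect sizes are
#' independent of the genotype draw.
#'
#' @param Gstd A `std_genotypes` object.
#' @param config A [simulation_config()].
#' @return A `phenotype_vector` with fields `values`, `causal_indices`,
#'   `weights`.
#' @export
simulate_phenotype <- function(Gstd, config) {
  stopifnot(inherits(Gstd, "std_genotypes"), inherits(config, "simulation_config"))
  p <- ncol(Gstd$values)
  K <- as.integer(round_half_up(config$causal_fraction * p))
  if (K < 1L) stop_ldrisk("causal_fraction * p rounds to zero causal SNPs")
  set.seed(config$seed + 1L)
  causal <- sort(sample.int(p, K))
  w <- stats::rnorm(K, 0, config$w_sd)
  eps <- stats::rnorm(nrow(Gstd$values), 0, config$noise_sd)
  y <- drop(Gstd$values[, causal, drop = FALSE] %*% w) + eps
  structure(list(values = y, causal_indices = causal, weights = w),
            class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("phenotype_vector: n=%d, K=%d causal SNPs, var(Y)=%.3f\n",
              length(x$values), length(x$causal_indices), var_pop(x$values)))
  invisible(x)
}

#' Random train/test partition of sample indices
#'
#' Uniformly selects `floor(train_fraction * n)` training samples; the rest
#' form the test set. With `n = 1092` and the default 0.8 fraction this gives
#' the 873/219 split used in the simulation design.
#'
#' @param n Total number of samples.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return A `data_split` with sorted integer fields `train_indices` and
#'   `test_indices`.
#' @examples
#' s <- split_data(1092, 0.8, seed = 1)
#' lengths(s[c("train_indices", "test_indices")])
#' @export
split_data <- function(n, train_fraction = 0.8, seed = 1L) {
  n <- assert_count(n, "n", min = 2L)
  train_fraction <- assert_number(train_fraction, "train_fraction", 0, 1,
                                  strict_lower = TRUE, strict_upper = TRUE)
  # guard against 0.8 * 1092 evaluating just below 873.6 in floating point
  n_tr <- as.integer(floor(train_fraction * n + 1e-9))
  if (n_tr < 1L || n_tr >= n) stop_ldrisk("split leaves an empty train or test set")
  set.seed(assert_count(seed, "seed", min = 0L))
  tr <- sort(sample.int(n, n_tr))
  structure(list(train_indices = tr,
                 test_indices = setdiff(seq_len(n), tr)),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("data_split: %d train / %d test\n",
              length(x$train_indices), length(x$test_indices)))
  invisible(x)
}
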