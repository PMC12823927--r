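# Test error in both modes: direct MSE for individual-level predictions and
# the bootstrap approximation for summary mode, with its exact all-pairs
# (B -> infinity) limit as an oracle.

#' Individual-level test mean squared error
#'
#' @param model A fitted individual-mode `ldrisk_model` (or `ldrisk_fit`).
#' @param x Test inputs (`std_genotypes` rows or matrix).
#' @param y Test trait values.
#' @return Test MSE.
#' @export
test_error_individual <- function(model, x, y) {
  if (inherits(model, "ldrisk_fit")) model <- model$model
  if (model$spec$output_dim != 1L) {
    stop_ldrisk("test_error_individual() needs an individual-mode model")
  }
  mse_loss(predict(model, x), y)
}

#' Bootstrap approximation of summary-mode test error
#'
#' The trained summary model, fed the *test* LD matrix, emits `n_tr` outputs
#' `O_1..O_n_tr`. For each of `B` resamples, `n_te` outputs are drawn
#' uniformly with replacement and paired in order with the test responses;
#' `TE_b` is their mean squared difference and the estimate is
#' `TE-hat = mean(TE_1..TE_B)`. Its `B -> Inf` limit is the all-pairs mean
#' computed exactly by [allpairs_oracle()].
#'
#' @param outputs Numeric vector of model outputs (length `n_tr`); a matrix
#'   of per-block outputs is averaged over rows first.
#' @param y_test Test responses (length `n_te`).
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return A `bootstrap_estimate`: `te_hat`, `resample_errors` (length `B`),
#'   `B`, `mc_se` (`sd(resample_errors)/sqrt(B)`), `seed`.
#' @examples
#' b <- bootstrap_test_error(rnorm(100), rnorm(30), B = 500, seed = 1)
#' b$te_hat
#' @export
bootstrap_test_error <- function(outputs, y_test, B = 1000L, seed = 1L) {
  if (is.matrix(outputs)) outputs <- colMeans(outputs)
  outputs <- as.numeric(outputs)
  if (length(outputs) == 0L || length(y_test) == 0L) {
    stop_ldrisk("outputs and y_test must be non-empty")
  }
  if (!all(is.finite(outputs))) stop_ldrisk("outputs contain non-finite values")
  B <- assert_count(B, "B")
  n_tr <- length(outputs)
  n_te <- length(y_test)
  set.seed(assert_count(seed, "seed", min = 0L))
  draws <- matrix(sample.int(n_tr, n_te * B, replace = TRUE), n_te, B)
  te <- colMeans((matrix(outputs[draws], n_te, B) - y_test)^2)
  structure(list(te_hat = mean(te), resample_errors = te, B = B,
                 mc_se = stats::sd(te) / sqrt(B), seed = as.integer(seed)),
            class = "bootstrap_estimate")
}

#' @export
print.bootstrap_estimate <- function(x, ...) {
  cat(sprintf("bootstrap_estimate: TE-hat = %.4f (MC se %.2g, B = %d)\n",
              x$te_hat, x$mc_se, x$B))
  invisible(x)
}

#' Exact all-pairs limit of the bootstrap test error
#'
#' `(1/(n_tr * n_te)) sum_j sum_i (O_j - y_i)^2`, which equals
#' `Var_pop(O) + Var_pop(y) + (mean(O) - mean(y))^2` algebraically. This is
#' the expectation of the resampled test error for any `B` and its limit as
#' `B -> Inf`.
#'
#' @param outputs Model outputs.
#' @param y_test Test responses.
#' @return A single number.
#' @export
allpairs_oracle <- function(outputs, y_test) {
  if (is.matrix(outputs)) outputs <- colMeans(outputs)
  outputs <- as.numeric(outputs)
  if (length(outputs) == 0L || length(y_test) == 0L) {
    stop_ldrisk("outputs and y_test must be non-empty")
  }
  var_pop(outputs) + var_pop(y_test) + (mean(outputs) - mean(y_test))^2
}

#' Repeat the simulation experiment across random splits
#'
#' For each repetition: draw a fresh train/test split of the fixed synthetic
#' panel (optionally redrawing the phenotype), fit the requested model
#' presets in individual and/or summary mode, and record training error,
#' individual-level test MSE, and the bootstrap summary test error with its
#' Monte-Carlo se. Results are summarized per (method, mode) cell as
#' mean (sd) over repetitions -- the layout of the simulation comparison
#' table.
#'
#' @param sim_config A [simulation_config()]; the panel is generated once
#'   from it.
#' @param methods Character vector of model preset names.
#' @param modes Which input modes to run; any of `"individual"`,
#'   `"summary"`.
#' @param R Number of repetitions.
#' @param B Bootstrap resamples per summary evaluation.
#' @param block_size Diagonal block size for CNN/transformer summary input;
#'   default one block covering the whole matrix.
#' @param redraw_phenotypes Redraw effect sizes and noise each repetition?
#'   Default `FALSE`: only the split is redrawn.
#' @param train_configs Optional named list of [train_config()] overrides
#'   per preset; defaults to each preset's reference schedule.
#' @param seed Master seed; repetition r uses `seed + r` for its split and
#'   fits.
#' @return A tibble with one row per (method, mode) and columns
#'   `train_mean`, `train_sd`, `test_mean`, `test_sd`, `n_reps`; per-rep
#'   records in `attr(, "details")`.
#' @export
replicate_experiment <- function(sim_config, methods = c("dnn-paper", "lstm-paper"),
                                 modes = c("individual", "summary"),
                                 R = 20L, B = 1000L, block_size = NULL,
                                 redraw_phenotypes = FALSE,
                                 train_configs = NULL, seed = 1L) {
  stopifnot(inherits(sim_config, "simulation_config"))
  R <- assert_count(R, "R")
  modes <- match.arg(modes, c("individual", "summary"), several.ok = TRUE)
  G <- simulate_genotypes(sim_config)
  G <- filter_maf(G, sim_config$maf_range[1])
  Gstd <- standardize_genotypes(G)
  n <- nrow(Gstd$values)
  pheno <- simulate_phenotype(Gstd, sim_config)
  rows <- list()
  for (r in seq_len(R)) {
    rep_seed <- seed + r
    if (redraw_phenotypes && r > 1L) {
      cfg_r <- sim_config
      cfg_r$seed <- sim_config$seed + r
      pheno <- simulate_phenotype(Gstd, cfg_r)
    }
    sp <- split_data(n, sim_config$train_fraction, seed = rep_seed)
    y_tr <- pheno$values[sp$train_indices]
    y_te <- pheno$values[sp$test_indices]
    x_tr <- Gstd$values[sp$train_indices, , drop = FALSE]
    x_te <- Gstd$values[sp$test_indices, , drop = FALSE]
    ld_tr <- compute_ld(Gstd, sp$train_indices)
    ld_te <- compute_ld(Gstd, sp$test_indices)
    for (m in methods) {
      tc_name <- default_train_preset(m)
      for (mode in modes) {
        tc <- if (!is.null(train_configs[[m]])) train_configs[[m]]
              else train_preset(tc_name, seed = rep_seed)
        tc$seed <- rep_seed
        res <- tryCatch(
          run_one_fit(m, mode, x_tr, y_tr, x_te, y_te, ld_tr, ld_te,
                      block_size, tc, B, rep_seed),
          error = function(e) stop_ldrisk(sprintf(
            "repetition %d, %s/%s failed: %s", r, m, mode, conditionMessage(e))))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          rep = r, method = m, mode = mode,
          train_error = res$train_error, test_error = res$test_error,
          test_mc_se = res$mc_se, var_y_test = var_pop(y_te))
      }
    }
  }
  details <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(train_error, test_error) ~ method + mode,
                          data = details, FUN = function(v) c(mean(v), stats::sd(v)))
  out <- tibble::tibble(
    method = agg$method, mode = agg$mode,
    train_mean = agg$train_error[, 1L], train_sd = agg$train_error[, 2L],
    test_mean = agg$test_error[, 1L], test_sd = agg$test_error[, 2L],
    n_reps = R)
  attr(out, "details") <- details
  out
}

run_one_fit <- function(preset, mode, x_tr, y_tr, x_te, y_te, ld_tr, ld_te,
                        block_size, tc, B, seed) {
  if (mode == "individual") {
    name <- if (grepl("-2d", preset)) sub("-2d", "", preset) else preset
    spec <- model_preset(name, input_mode = "individual")
    model <- build_model(spec, infer_input_shape(spec, x_tr), seed = seed)
    fit <- fit_individual(model, x_tr, y_tr, tc)
    list(train_error = fit$final_train_error,
         test_error = test_error_individual(fit, x_te, y_te),
         mc_se = NA_real_)
  } else {
    name <- summary_preset_name(preset)
    spec <- model_preset(name, input_mode = "summary", n_train = length(y_tr))
    in_tr <- summary_input(spec, ld_tr, block_size)
    in_te <- summary_input(spec, ld_te, block_size)
    model <- build_model(spec, infer_input_shape(spec, in_tr), seed = seed)
    fit <- fit_summary(model, in_tr, y_tr, tc)
    outputs <- predict(fit$model, in_te)
    bt <- bootstrap_test_error(outputs, y_te, B = B, seed = seed)
    list(train_error = fit$final_train_error, test_error = bt$te_hat,
         mc_se = bt$mc_se)
  }
}

# 1D CNN presets switch to their 2D twins on LD input
summary_preset_name <- function(preset) {
  if (grepl("^cnn", preset) && !grepl("-2d", preset)) paste0(preset, "-2d")
  else preset
}

summary_input <- function(spec, ld, block_size) {
  if (spec$family %in% c("cnn2d", "transformer")) {
    partition_blocks(ld, block_size %||% ncol(ld$values))
  } else ld
}
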