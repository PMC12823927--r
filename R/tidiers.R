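# broom-style tidiers and ggplot2 autoplot methods for result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' @param x An `ldrisk_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `loss`, `mode`,
#'   `model`.
#' @export
tidy.ldrisk_fit <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history),
                 loss = x$loss_history,
                 mode = x$mode,
                 model = x$model$spec$name)
}

#' One-row summary of a training run
#'
#' @param x An `ldrisk_fit`.
#' @param ... Unused.
#' @return A tibble: model, mode, epochs, final training error, parameters.
#' @export
glance.ldrisk_fit <- function(x, ...) {
  tibble::tibble(model = x$model$spec$name, mode = x$mode,
                 epochs = length(x$loss_history),
                 final_train_error = x$final_train_error,
                 n_parameters = n_parameters(x$model))
}

#' Tidy a bootstrap test-error estimate
#'
#' @param x A `bootstrap_estimate`.
#' @param ... Unused.
#' @return A tibble with one row per resample: `resample`, `te`.
#' @export
tidy.bootstrap_estimate <- function(x, ...) {
  tibble::tibble(resample = seq_len(x$B), te = x$resample_errors)
}

#' One-row summary of a bootstrap estimate
#'
#' @param x A `bootstrap_estimate`.
#' @param ... Unused.
#' @return A tibble: `te_hat`, `mc_se`, `B`, `seed`.
#' @export
glance.bootstrap_estimate <- function(x, ...) {
  tibble::tibble(te_hat = x$te_hat, mc_se = x$mc_se, B = x$B, seed = x$seed)
}

#' Plot the training loss curve
#'
#' @param object An `ldrisk_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ldrisk_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training MSE",
                  title = sprintf("%s (%s mode)", object$model$spec$name,
                                  object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap test-error distribution
#'
#' @param object A `bootstrap_estimate`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bootstrap_estimate <- function(object, bins = 40, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$te)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(xintercept = object$te_hat, linetype = 2) +
    ggplot2::labs(x = "resampled test error", y = "count",
                  title = sprintf("TE-hat = %.3f (B = %d)", object$te_hat,
                                  object$B)) +
    ggplot2::theme_minimal()
}

#' Heatmap of an LD matrix
#'
#' @param object An `ld_matrix`.
#' @param max_snps Downsample to at most this many SNPs for display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ld_matrix <- function(object, max_snps = 200, ...) {
  m <- object$values
  p <- ncol(m)
  idx <- if (p > max_snps) round(seq(1, p, length.out = max_snps)) else seq_len(p)
  d <- expand.grid(i = idx, j = idx)
  d$r <- m[cbind(d$i, d$j)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(limits = range(d$r)) +
    ggplot2::labs(x = "SNP", y = "SNP", fill = "LD") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
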