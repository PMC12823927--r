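# Best linear unbiased prediction under the standard genomic mixed model
#   y = 1*mu + Z u + e,  u ~ N(0, sigma_u^2 I_p),  e ~ N(0, sigma_e^2 I_n),
# with Z the standardized genotype rows. REML estimation of the two variance
# components works in the eigenbasis of the genomic kernel Z Z', which makes
# the profiled criterion a cheap 1-D optimization; prediction is the ridge
# solution with penalty lambda = sigma_e^2 / sigma_u^2.

#' Estimate mixed-model variance components by REML
#'
#' Profiles the restricted likelihood over the variance ratio
#' `delta = sigma_e^2 / sigma_u^2` using the eigendecomposition of the
#' genomic kernel `Z Z'` after projecting out the intercept (the only fixed
#' effect), then recovers `sigma_u^2` in closed form. Falls back to a
#' Haseman-Elston-style method-of-moments estimate with a warning if the
#' REML optimization fails.
#'
#' @param Gstd_train Training rows: `std_genotypes` or numeric matrix.
#' @param y_train Training trait values.
#' @return A `variance_components` list: `sigma_u2`, `sigma_e2`,
#'   `method` (`"reml"` or `"moments"`), `loglik`.
#' @export
estimate_variance_components <- function(Gstd_train, y_train) {
  Z <- if (inherits(Gstd_train, "std_genotypes")) Gstd_train$values else Gstd_train
  n <- nrow(Z)
  if (n < 2L || n != length(y_train)) {
    stop_ldrisk("need >= 2 training samples with matching phenotype length")
  }
  yc <- y_train - mean(y_train)
  K <- tcrossprod(Z)
  # center the kernel: eigenbasis of P K P with P = I - 11'/n spans the
  # intercept-free contrasts used by REML
  K <- sweep(K, 1L, rowMeans(K))
  K <- sweep(K, 2L, colMeans(K))
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- seq_len(n - 1L)                    # one eigenvalue is ~0 (the 1 vector)
  lam <- pmax(eg$values[keep], 0)
  eta <- drop(crossprod(eg$vectors[, keep, drop = FALSE], yc))
  m <- length(keep)
  # restricted log-likelihood profiled over sigma_u^2, as a function of
  # log(delta); constant terms dropped
  nll <- function(logd) {
    d <- exp(logd)
    w <- lam + d
    s2u <- sum(eta^2 / w) / m
    0.5 * (m * log(s2u) + sum(log(w)))
  }
  opt <- tryCatch(stats::optimize(nll, c(-25, 25)), error = function(e) NULL)
  if (!is.null(opt)) {
    d <- exp(opt$minimum)
    s2u <- sum(eta^2 / (lam + d)) / m
    vc <- list(sigma_u2 = s2u, sigma_e2 = s2u * d, method = "reml",
               loglik = -opt$objective)
    # boundary fits (all-noise / all-signal) are still valid estimates
    return(structure(vc, class = "variance_components"))
  }
  warning("REML optimization failed; using method-of-moments estimates")
  # moments: regress squared contrasts on the kernel (Haseman-Elston)
  num <- sum(K * (tcrossprod(yc) - diag(var_pop(yc), n)))
  den <- sum(K^2) - sum(diag(K)^2)
  s2u <- max(num / den, 0)
  s2e <- max(var_pop(yc) - s2u * mean(diag(K)), 1e-8)
  structure(list(sigma_u2 = s2u, sigma_e2 = s2e, method = "moments",
                 loglik = NA_real_),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components (%s): sigma_u2 = %.4g, sigma_e2 = %.4g\n",
              x$method, x$sigma_u2, x$sigma_e2))
  invisible(x)
}

#' BLUP predictions for new individuals
#'
#' Computes `u_hat = Z_tr' (Z_tr Z_tr' + lambda I)^-1 (y - ybar)` with
#' `lambda = sigma_e^2 / sigma_u^2` and returns
#' `ybar + Z_te u_hat` -- identical to ridge regression with penalty
#' `lambda` (Woodbury identity), with the intercept as the only fixed
#' effect. If `sigma_u2 = 0` the training mean is predicted.
#'
#' @param Gstd_train,Gstd_test Training/test rows (`std_genotypes` or
#'   matrices over the same SNPs).
#' @param y_train Training trait values.
#' @param vc A `variance_components` object, or `NULL` to estimate by REML.
#' @return Numeric predictions, one per test row.
#' @examples
#' Z <- matrix(rnorm(60), 20, 3)
#' y <- Z %*% c(1, -1, 0.5) + rnorm(20, sd = 0.1)
#' blup_predict(Z, drop(y), Z[1:5, ],
#'              vc = structure(list(sigma_u2 = 1, sigma_e2 = 1),
#'                             class = "variance_components"))
#' @export
blup_predict <- function(Gstd_train, y_train, Gstd_test, vc = NULL) {
  Ztr <- if (inherits(Gstd_train, "std_genotypes")) Gstd_train$values else Gstd_train
  Zte <- if (inherits(Gstd_test, "std_genotypes")) Gstd_test$values else Gstd_test
  if (ncol(Ztr) != ncol(Zte)) stop_ldrisk("train and test SNP counts differ")
  if (nrow(Ztr) != length(y_train)) stop_ldrisk("dimension mismatch")
  if (is.null(vc)) vc <- estimate_variance_components(Ztr, y_train)
  mu <- mean(y_train)
  if (vc$sigma_u2 <= 0) return(rep(mu, nrow(Zte)))
  lambda <- vc$sigma_e2 / vc$sigma_u2
  n <- nrow(Ztr)
  a <- solve(tcrossprod(Ztr) + diag(lambda, n), y_train - mu)
  u_hat <- crossprod(Ztr, a)
  drop(mu + Zte %*% u_hat)
}
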