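# LD summary matrices and their preparation as model inputs:
# scaled Gram matrices, diagonal-block partitions, upper-triangle
# vectorization and sliding windows.

new_ld_matrix <- function(values, snp_ids, n_source) {
  structure(list(values = values, snp_ids = snp_ids,
                 n_source = as.integer(n_source)),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d x %d from %d individuals\n",
              nrow(x$values), ncol(x$values), x$n_source))
  invisible(x)
}

#' @export
dim.ld_matrix <- function(x) dim(x$values)

#' Compute an LD matrix from standardized genotypes
#'
#' Returns `(1/|rows|) X'X` where `X` is the selected row submatrix of the
#' standardized genotypes -- the scaled Gram matrix summarizing pairwise
#' SNP correlation. Computing it separately on the training and test rows
#' yields the two summary inputs of the summary-data workflow.
#'
#' @param Gstd A `std_genotypes` object.
#' @param rows Sample indices to use; default all rows.
#' @return An `ld_matrix` with fields `values`, `snp_ids`, `n_source`.
#' @examples
#' G <- simulate_genotypes(simulation_config(100, 40, seed = 1))
#' ld <- compute_ld(standardize_genotypes(G))
#' @export
compute_ld <- function(Gstd, rows = NULL) {
  stopifnot(inherits(Gstd, "std_genotypes"))
  if (is.null(rows)) rows <- seq_len(nrow(Gstd$values))
  if (length(rows) == 0L) stop_ldrisk("`rows` must be non-empty")
  x <- Gstd$values[rows, , drop = FALSE]
  v <- crossprod(x) / length(rows)
  v <- (v + t(v)) / 2                       # enforce exact symmetry
  new_ld_matrix(v, snp_ids = Gstd$snp_ids, n_source = length(rows))
}

#' Plan a diagonal-block partition
#'
#' Index arithmetic behind [partition_blocks()]: consecutive intervals of
#' `block_size` SNPs along the diagonal, with a short final interval when
#' `p` is not divisible by `block_size`.
#'
#' @param p Number of SNPs.
#' @param block_size Block side length.
#' @return A tibble with columns `block`, `start`, `end`, `padded`.
#' @examples
#' nrow(block_plan(8299, 193))  # 43
#' @export
block_plan <- function(p, block_size) {
  p <- assert_count(p, "p")
  block_size <- assert_count(block_size, "block_size")
  if (block_size > p) stop_ldrisk("block_size exceeds the number of SNPs")
  n_blocks <- ceiling(p / block_size)
  start <- (seq_len(n_blocks) - 1L) * block_size + 1L
  end <- pmin(start + block_size - 1L, p)
  tibble::tibble(block = seq_len(n_blocks), start = start, end = end,
                 padded = (end - start + 1L) < block_size)
}

#' Partition an LD matrix into diagonal blocks
#'
#' Cuts the p x p LD matrix into consecutive `block_size` x `block_size`
#' submatrices along the diagonal -- the computationally tractable inputs
#' used by the convolutional and transformer summary models. LD is largely
#' local (haplotype blocks), so the diagonal band retains most of the
#' correlation structure. When `p` is not divisible by `block_size` the
#' final short block is zero-padded up to full size and flagged.
#'
#' @param ld An `ld_matrix`.
#' @param block_size Block side length (e.g. 193 so that 8299 SNPs give
#'   exactly 43 blocks).
#' @return An `ld_block_set`: fields `blocks` (list of b x b matrices),
#'   `block_size`, `n_blocks`, `index_ranges` (the [block_plan()] tibble),
#'   `padded`.
#' @export
partition_blocks <- function(ld, block_size) {
  stopifnot(inherits(ld, "ld_matrix"))
  p <- ncol(ld$values)
  plan <- block_plan(p, block_size)
  blocks <- lapply(seq_len(nrow(plan)), function(i) {
    idx <- plan$start[i]:plan$end[i]
    b <- ld$values[idx, idx, drop = FALSE]
    if (length(idx) < block_size) {
      full <- matrix(0, block_size, block_size)
      full[seq_along(idx), seq_along(idx)] <- b
      b <- full
    }
    b
  })
  structure(list(blocks = blocks,
                 block_size = as.integer(block_size),
                 n_blocks = nrow(plan),
                 index_ranges = plan,
                 padded = any(plan$padded)),
            class = "ld_block_set")
}

#' @export
print.ld_block_set <- function(x, ...) {
  cat(sprintf("ld_block_set: %d blocks of %d x %d%s\n", x$n_blocks,
              x$block_size, x$block_size,
              if (x$padded) " (last block zero-padded)" else ""))
  invisible(x)
}

#' Vectorize the upper triangle of an LD matrix
#'
#' Row-major concatenation of the entries with column index >= row (or
#' strictly >). Because the LD matrix is symmetric this loses no
#' information; it is the input representation used by the dense summary
#' model.
#'
#' @param ld An `ld_matrix` or plain square matrix.
#' @param include_diagonal Keep the diagonal? Default `TRUE`.
#' @return Numeric vector of length `p(p+1)/2` (with diagonal) or
#'   `p(p-1)/2`.
#' @export
upper_triangle <- function(ld, include_diagonal = TRUE) {
  m <- if (inherits(ld, "ld_matrix")) ld$values else ld
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  # row-major upper triangle == column-major lower triangle of the transpose
  t(m)[lower.tri(m, diag = include_diagonal)]
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' Inverse of [upper_triangle()]; exact for symmetric input.
#'
#' @param v Vector produced by [upper_triangle()].
#' @param p Matrix dimension.
#' @param include_diagonal Whether `v` includes the diagonal.
#' @param diag_values Diagonal to restore when `include_diagonal = FALSE`.
#' @return A p x p symmetric matrix.
#' @export
ld_from_upper_triangle <- function(v, p, include_diagonal = TRUE,
                                   diag_values = NULL) {
  expected <- if (include_diagonal) p * (p + 1) / 2 else p * (p - 1) / 2
  if (length(v) != expected) stop_ldrisk("vector length does not match p")
  m <- matrix(0, p, p)
  tm <- t(m)
  tm[lower.tri(tm, diag = include_diagonal)] <- v
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  if (!include_diagonal && !is.null(diag_values)) diag(m) <- diag_values
  m
}

#' Sliding-window index intervals over a SNP sequence
#'
#' Intervals `[start, start + window)` for `start = 0, stride, 2*stride, ...`
#' while the window fits (reported 1-based inclusive). With `p = 8299`,
#' `window = 1000`, `stride = 500` this yields the 15 overlapping windows of
#' the transformer's individual-level input. By default a final window
#' ending exactly at `p` is appended (and flagged) when the strided windows
#' do not reach the last SNP; `strict_paper = TRUE` drops that trailing
#' window, leaving the tail uncovered.
#'
#' @param p Sequence length.
#' @param window Window length.
#' @param stride Stride between window starts.
#' @param strict_paper Only keep the strided windows.
#' @return A tibble with columns `start`, `end` (1-based inclusive) and
#'   `partial` (`TRUE` for the appended trailing window).
#' @examples
#' window_slices(8299, 1000, 500, strict_paper = TRUE)
#' @export
window_slices <- function(p, window, stride, strict_paper = FALSE) {
  p <- assert_count(p, "p")
  window <- assert_count(window, "window")
  stride <- assert_count(stride, "stride")
  if (window > p) stop_ldrisk("window exceeds sequence length")
  starts0 <- seq.int(0L, p - window, by = stride)
  partial <- rep(FALSE, length(starts0))
  last_end <- starts0[length(starts0)] + window
  if (!strict_paper && last_end < p) {
    starts0 <- c(starts0, p - window)
    partial <- c(partial, TRUE)
  }
  tibble::tibble(start = starts0 + 1L, end = starts0 + window,
                 partial = partial)
}
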