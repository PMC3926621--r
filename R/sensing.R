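#' Sparse binary sensing
#'
#' The sensor projects each demeaned channel with one shared `M x N` binary
#' matrix holding exactly `d` ones per column.  Because every entry is 0 or
#' 1, the projection costs `N*d` additions per channel and no
#' multiplications — the property that makes compressed sensing viable on
#' a battery-powered node.  The matrix is never transmitted: the header
#' carries `(M, N, d, seed)` and both ends regenerate it bit-exactly.
#'
#' @name sensing
NULL

#' Generate a sparse binary measurement matrix
#'
#' For each of the `N` columns, `d` distinct row indices are drawn
#' uniformly without replacement and set to 1.  Columns are sampled
#' independently; the same seed always reproduces the same pattern.
#'
#' @param M number of measurements (rows).
#' @param N signal length (columns).
#' @param d ones per column, `1 <= d <= M` (default 8: reconstruction
#'   quality saturates there and smaller `d` means fewer additions).
#' @param seed integer RNG seed; part of the matrix identity.
#' @return Object of class `sparse_binary_matrix` with fields `M`, `N`,
#'   `d`, `seed` and `pattern` (`d x N` integer matrix of row indices).
#' @export
sparse_binary_matrix <- function(M, N, d = 8L, seed = 1L) {
  M <- as.integer(M); N <- as.integer(N); d <- as.integer(d)
  if (d < 1L || d > M) stop("require 1 <= d <= M")
  if (M > N) stop("require M <= N")
  pattern <- with_local_seed(seed, {
    vapply(seq_len(N), function(j) sort(sample.int(M, d)), integer(d))
  })
  pattern <- matrix(pattern, nrow = d, ncol = N)
  structure(list(M = M, N = N, d = d, seed = as.integer(seed),
                 pattern = pattern),
            class = "sparse_binary_matrix")
}

#' @export
print.sparse_binary_matrix <- function(x, ...) {
  cat(sprintf("<sparse_binary_matrix> %d x %d, d = %d, seed = %d\n",
              x$M, x$N, x$d, x$seed))
  invisible(x)
}

#' Dense / sparse-Matrix views of a sensing matrix
#'
#' @param phi a `sparse_binary_matrix`.
#' @return `as_dense_matrix()`: base `M x N` 0/1 matrix;
#'   `as_sparse_Matrix()`: a [Matrix::sparseMatrix()].
#' @export
as_dense_matrix <- function(phi) {
  m <- matrix(0, phi$M, phi$N)
  m[cbind(as.vector(phi$pattern), rep(seq_len(phi$N), each = phi$d))] <- 1
  m
}

#' @rdname as_dense_matrix
#' @export
as_sparse_Matrix <- function(phi) {
  Matrix::sparseMatrix(i = as.vector(phi$pattern),
                       j = rep(seq_len(phi$N), each = phi$d),
                       x = 1, dims = c(phi$M, phi$N))
}

#' Project an epoch with a sparse binary matrix
#'
#' Computes `Y[, j] = Phi %*% Ftilde[, j]` for every channel using only
#' index-gather additions (grouped sums over the stored row-index pattern),
#' mirroring what the sensor microcontroller would execute.
#'
#' @param phi a `sparse_binary_matrix`.
#' @param e a `demeaned_epoch` or `N x C` matrix.
#' @return `M x C` matrix of compressed measurements.
#' @export
project_epoch <- function(phi, e) {
  Ft <- if (inherits(e, "demeaned_epoch")) e$Ftilde else as.matrix(e)
  if (nrow(Ft) != phi$N)
    stop(sprintf("epoch length %d does not match matrix N = %d", nrow(Ft), phi$N))
  idx <- as.vector(phi$pattern)                       # length d*N
  V <- Ft[rep(seq_len(phi$N), each = phi$d), , drop = FALSE]
  S <- rowsum(V, group = idx)                         # sums per touched row
  Y <- matrix(0, phi$M, ncol(Ft))
  Y[as.integer(rownames(S)), ] <- S
  Y
}

#' Sensor-side addition count of the projection stage
#'
#' Each channel costs `N*d` additions; the difference-coding stage is
#' counted separately (`M` subtractions per paired channel).
#'
#' @param phi a `sparse_binary_matrix`.
#' @param C channel count.
#' @return Integer-valued count `C * N * d`.
#' @export
sensor_op_count <- function(phi, C) {
  as.numeric(C) * phi$N * phi$d
}
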