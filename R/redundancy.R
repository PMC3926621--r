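#' Interchannel redundancy removal
#'
#' Spatially close EEG channels are highly correlated, and because every
#' channel is projected with the same sensing matrix the correlation
#' carries over to the measurement vectors.  The server selects channel
#' pairs greedily by absolute Pearson correlation of the measurement
#' columns (threshold `T`, default 0.6), keeping only pairs whose signed
#' incidence rows are linearly independent so the resulting `C x C` system
#' is invertible, and fills any remaining slots with minimum-variance
#' singleton channels.  The sensor then transmits sign-matched differences
#' `y_i - sign(R_ij) * y_j`, whose narrower distribution entropy-codes in
#' fewer bits; the server inverts the schedule exactly.
#'
#' @name redundancy
NULL

#' Pearson correlation matrix of measurement columns
#'
#' @param Y `M x C` measurement block.
#' @return `C x C` correlation matrix; columns with zero variance get
#'   correlation 0 against everything (with a warning) and 1 on the
#'   diagonal.
#' @export
correlation_matrix <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 measurements per channel")
  sds <- apply(Y, 2L, sd)
  R <- suppressWarnings(cor(Y))
  if (any(sds == 0)) {
    warning("zero-variance measurement column; its correlations set to 0")
    R[is.na(R)] <- 0
  }
  diag(R) <- 1
  R
}

#' Select the difference-coding schedule (pair list)
#'
#' Greedy selection: repeatedly take the largest remaining `|R[i, j]|`
#' (ties broken by smallest `(i, j)` lexicographically), discard candidates
#' whose signed incidence row `e_i - sign(R_ij) e_j` is linearly dependent
#' on the rows already chosen, and stop pairing when `C` entries are found
#' or the best remaining correlation falls below `T`.  Remaining slots are
#' filled with singleton channels `(i, 0)` in order of increasing
#' measurement variance, skipping dependent ones, so the returned system
#' always has full rank `C`.
#'
#' @param R `C x C` correlation matrix.
#' @param variances length-`C` vector of measurement column variances
#'   (used for the singleton fallback).
#' @param T correlation threshold in `[0, 1]` (default 0.6).
#' @param tol rank tolerance for the independence test.
#' @return Object of class `pair_list`: data frame with columns `i`, `j`
#'   (`j = 0` marks a singleton) and `sign`, plus attribute `T`.
#' @export
select_pairs <- function(R, variances, T = 0.6, tol = 1e-10) {
  C <- nrow(R)
  stopifnot(ncol(R) == C, length(variances) == C)
  if (C == 1L) {
    return(structure(data.frame(i = 1L, j = 0L, sign = 1),
                     T = T, class = c("pair_list", "data.frame")))
  }
  ut <- which(upper.tri(R), arr.ind = TRUE)
  cand <- data.frame(i = ut[, 1L], j = ut[, 2L], r = R[ut])
  cand <- cand[order(-abs(cand$r), cand$i, cand$j), , drop = FALSE]

  Q <- matrix(0, nrow = 0L, ncol = C)    # orthonormal basis of chosen rows
  entries <- list()
  indep <- function(row) {
    resid <- row
    if (nrow(Q) > 0L) resid <- resid - drop(crossprod(Q, Q %*% resid))
    nr <- sqrt(sum(resid^2))
    if (nr <= tol * sqrt(sum(row^2))) return(NULL)
    resid / nr
  }
  for (k in seq_len(nrow(cand))) {
    if (length(entries) >= C) break
    if (abs(cand$r[k]) < T) break
    s <- if (cand$r[k] >= 0) 1 else -1
    row <- numeric(C); row[cand$i[k]] <- 1; row[cand$j[k]] <- -s
    q <- indep(row)
    if (!is.null(q)) {
      Q <- rbind(Q, q)
      entries[[length(entries) + 1L]] <- c(cand$i[k], cand$j[k], s)
    }
  }
  if (length(entries) < C) {
    for (ch in order(variances, seq_len(C))) {
      if (length(entries) >= C) break
      row <- numeric(C); row[ch] <- 1
      q <- indep(row)
      if (!is.null(q)) {
        Q <- rbind(Q, q)
        entries[[length(entries) + 1L]] <- c(ch, 0L, 1)
      }
    }
  }
  m <- do.call(rbind, entries)
  structure(data.frame(i = as.integer(m[, 1L]), j = as.integer(m[, 2L]),
                       sign = m[, 3L]),
            T = T, class = c("pair_list", "data.frame"))
}

#' Signed incidence matrix of a pair list
#'
#' Row `k` is `e_{i_k} - sign_k e_{j_k}` (just `e_{i_k}` for singletons);
#' full rank of this matrix is what makes the difference schedule
#' invertible.
#'
#' @param p a `pair_list`.
#' @param C channel count.
#' @return `C x C` matrix.
#' @export
pair_incidence <- function(p, C = max(p$i, p$j)) {
  A <- matrix(0, nrow(p), C)
  for (k in seq_len(nrow(p))) {
    A[k, p$i[k]] <- 1
    if (p$j[k] > 0L) A[k, p$j[k]] <- A[k, p$j[k]] - p$sign[k]
  }
  A
}

#' Sensor-side difference coding
#'
#' Column `k` of the output is `y_{i_k} - sign_k * y_{j_k}` (a copy of
#' `y_{i_k}` for singletons): `M` subtractions per true pair.
#'
#' @param Y `M x C` measurement block.
#' @param p a `pair_list` with `C` entries.
#' @return `M x C` difference block.
#' @export
apply_differences <- function(Y, p) {
  Y <- as.matrix(Y)
  C <- ncol(Y)
  if (nrow(p) != C) stop("pair list entry count does not match channels")
  if (any(p$i > C) || any(p$j > C)) stop("pair list index out of range")
  Yt <- matrix(0, nrow(Y), C)
  for (k in seq_len(C)) {
    Yt[, k] <- if (p$j[k] > 0L) Y[, p$i[k]] - p$sign[k] * Y[, p$j[k]] else Y[, p$i[k]]
  }
  Yt
}

#' Server-side inversion of the difference coding
#'
#' Solves the `C x C` signed incidence system for every measurement row;
#' exact up to floating point because the schedule is invertible by
#' construction.
#'
#' @param Yt `M x C` difference block.
#' @param p the `pair_list` used to produce it.
#' @return `M x C` measurement block.
#' @export
invert_differences <- function(Yt, p) {
  Yt <- as.matrix(Yt)
  A <- pair_incidence(p, ncol(Yt))
  sol <- tryCatch(solve(A, t(Yt)), error = function(e) NULL)
  if (is.null(sol)) {
    rk <- qr(A)$rank
    bad <- which(duplicated(A, MARGIN = 1))[1] %||% nrow(p)
    stop(sprintf(
      "pair list is singular (rank %d of %d); offending entry %d: (%d, %d)",
      rk, ncol(Yt), bad, p$i[bad], p$j[bad]))
  }
  t(sol)
}
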