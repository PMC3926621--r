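#' Server-side reconstruction
#'
#' The server decodes the bitstream, inverts the difference schedule and
#' recovers each channel independently by basis pursuit denoising (BPDN):
#' `min ||c||_1 subject to ||y - A c||_2 <= sigma` with `A = Phi Psi`, the
#' sensing matrix composed with the Gabor dictionary.  The solver is a
#' spectral projected-gradient method on the LASSO subproblem with Newton
#' root finding on the Pareto curve (the approach of the SPGL1 family).
#'
#' @name recon
NULL

#' Basis pursuit denoise solver
#'
#' Approximately solves `min ||c||_1 s.t. ||y - A c||_2 <= sigma`.  With
#' `sigma = 0` this is equality-constrained basis pursuit, solved to the
#' relative residual tolerance `bp_tol`.  The Pareto root (the value of the
#' l1 radius at which the LASSO residual equals `sigma`) is found by
#' Newton's method using the known derivative of the Pareto curve; each
#' LASSO subproblem is solved by nonmonotone spectral projected gradient
#' (compiled core).
#'
#' @param A dense `M x K` matrix (`Phi %*% Psi` for the codec path).
#' @param y length-`M` measurement vector.
#' @param sigma residual bound in measurement units (>= 0).
#' @param max_matvec total matrix-vector product budget; exceeding it
#'   returns the best iterate with `converged = FALSE`.
#' @param opt_tol duality-gap tolerance of the LASSO subproblems, and the
#'   relative residual slack accepted around `sigma`.
#' @param bp_tol relative residual target when `sigma = 0`.
#' @param max_inner iteration cap per LASSO subproblem.
#' @param max_outer cap on Pareto (Newton) iterations.
#' @return List with `coef`, `residual_norm`, `l1_norm`, `matvec`,
#'   `outer_iters`, `converged`.
#' @export
bpdn_solve <- function(A, y, sigma = 0, max_matvec = 20000L,
                       opt_tol = 1e-4, bp_tol = 1e-6, max_inner = 200L,
                       max_outer = 60L, polish = TRUE) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  res <- bpdn_spg_cpp(A, y, sigma, opt_tol, bp_tol,
                      as.integer(max_matvec), as.integer(max_inner),
                      as.integer(max_outer))
  res$coef <- as.numeric(res$coef)
  # For equality-constrained basis pursuit the SPG iterate identifies the
  # support long before the coefficients settle; a least-squares solve on
  # that support then reaches the exact solution in one step.  The polish
  # is accepted only when it is feasible to bp_tol and does not increase
  # the l1 norm; otherwise the solve is escalated with tighter tolerances
  # and the polish retried.
  if (polish && sigma == 0) {
    ynorm <- sqrt(sum(y^2))
    pol <- polish_bp(A, y, res, bp_tol, ynorm)
    if (is.null(pol)) {
      res2 <- bpdn_spg_cpp(A, y, sigma, opt_tol / 20, bp_tol,
                           as.integer(max_matvec * 8L),
                           as.integer(max_inner * 8L),
                           as.integer(max_outer * 2L))
      res2$coef <- as.numeric(res2$coef)
      res2$matvec <- res2$matvec + res$matvec
      res <- res2
      pol <- polish_bp(A, y, res, bp_tol, ynorm)
    }
    if (!is.null(pol)) res <- pol
  }
  res
}

# Attempt the active-set least-squares polish; NULL if not acceptable.
polish_bp <- function(A, y, res, bp_tol, ynorm) {
  if (all(res$coef == 0)) return(NULL)
  S <- which(abs(res$coef) > 1e-5 * max(abs(res$coef)))
  if (length(S) > nrow(A) %/% 2L) {
    S <- S[order(-abs(res$coef[S]))][seq_len(nrow(A) %/% 2L)]
  }
  cS <- qr.coef(qr(A[, S, drop = FALSE]), y)
  cS[is.na(cS)] <- 0
  resid <- sqrt(sum((y - A[, S, drop = FALSE] %*% cS)^2))
  if (resid > max(bp_tol * ynorm, 1e-12) ||
      sum(abs(cS)) > res$l1_norm * (1 + 1e-6)) return(NULL)
  res$coef[] <- 0
  res$coef[S] <- cS
  res$residual_norm <- resid
  res$l1_norm <- sum(abs(cS))
  res$converged <- TRUE
  res
}

#' Default BPDN residual bound from the quantizer step
#'
#' Uniform quantization error has variance `step^2 / 12` per measurement;
#' aggregated over `M` measurements its RMS norm is
#' `step * sqrt(M) / sqrt(12)`, which is used as the default `sigma`.
#'
#' @param q a [quantizer_spec()].
#' @param M measurement count.
#' @return Scalar sigma.
#' @export
default_sigma <- function(q, M) q$step * sqrt(M) / sqrt(12)

#' Reconstruction configuration
#'
#' The automatic residual bound for channel `j` is
#' `max(default_sigma(q, M), sigma_rel * ||y_j||)`: the quantization-noise
#' term plus a relative floor accounting for the part of a real signal
#' that no sparse Gabor combination represents (background activity).
#' Forcing the residual below that floor makes the solver spend most of
#' its iterations fitting background noise into dictionary atoms, which
#' costs an order of magnitude more compute without improving — and
#' eventually degrading — reconstruction quality.
#'
#' @param sigma explicit BPDN residual bound; `NULL` (default) uses the
#'   automatic rule above.
#' @param sigma_rel relative residual floor (fraction of `||y_j||`);
#'   default 0.05.  Set to 0 to recover the pure quantization rule.
#' @param max_matvec,opt_tol,bp_tol,max_inner passed to [bpdn_solve()].
#' @export
recon_config <- function(sigma = NULL, sigma_rel = 0.05,
                         max_matvec = 20000L, opt_tol = 1e-4,
                         bp_tol = 1e-6, max_inner = 200L) {
  structure(list(sigma = sigma, sigma_rel = sigma_rel,
                 max_matvec = max_matvec, opt_tol = opt_tol,
                 bp_tol = bp_tol, max_inner = max_inner),
            class = "recon_config")
}

#' Reconstruct an epoch from its compressed form
#'
#' Full server path: depacketize, Huffman decode, dequantize,
#' deinterleave, invert the difference schedule, solve BPDN per channel
#' against the Gabor dictionary, add back the channel means.  When packets
#' were lost, decoding resynchronizes at the next received run (using the
#' encoder's symbol positions), every measurement row with any missing
#' channel symbol is discarded, and the corresponding rows of the sensing
#' matrix are deleted before solving — measurement loss degrades the
#' solution gracefully instead of corrupting it.
#'
#' @param cz a `compressed_epoch`.
#' @param dict a [gabor_dictionary()] with matching `N`.
#' @param cfg a [recon_config()].
#' @param lost_packets integer vector of lost packet sequence numbers
#'   (empty for a perfect channel).
#' @param codebook offline codebook; defaults to the one stored with the
#'   epoch, and must match the header's codebook id.
#' @return Object of class `reconstructed_epoch`: `F_rec` (`N x C`),
#'   `diagnostics` (per-channel residual norm, l1 norm, matvecs,
#'   convergence flag), `rows_kept`, `rows_lost`.
#' @export
reconstruct_epoch <- function(cz, dict, cfg = recon_config(),
                              lost_packets = integer(0), codebook = NULL) {
  h <- decompress_header(cz)
  if (is.null(h$N) || is.null(h$C) || is.null(h$M))
    stop("corrupted header")
  cb <- codebook %||% cz$meta$codebook
  if (cb$id != h$codebook_id)
    stop("codebook id mismatch: decoder codebook differs from the header's")
  if (dict$N != h$N) stop("dictionary length does not match epoch length")
  q <- quantizer_spec(h$bits, h$lo, h$hi)
  M <- h$M; C <- h$C

  if (length(lost_packets) == 0L) {
    codes <- huffman_decode(depacketize(cz$packets), cb, h$n_symbols)
    sym_ok <- rep(TRUE, h$n_symbols)
    codes_full <- codes
  } else {
    if (is.null(cz$meta$sym_bitpos))
      stop("packet-loss reconstruction needs encoder symbol positions")
    dec <- decode_with_loss(cz, cb, lost_packets)
    sym_ok <- dec$sym_ok
    codes_full <- dec$codes
  }
  row_ok <- colSums(matrix(!sym_ok, nrow = C)) == 0L   # symbol k -> row ceil(k/C)
  keep <- which(row_ok)
  if (length(keep) == 0L) stop("all measurement rows lost")

  deq <- dequantize(codes_full, q)
  Yt <- deinterleave(deq, C)[keep, , drop = FALSE]
  Y <- invert_differences(Yt, h$pairs)

  phi <- sparse_binary_matrix(M, h$N, h$d, h$seed)
  A_full <- as.matrix(as_sparse_Matrix(phi) %*% dict$Psi)
  A <- A_full[keep, , drop = FALSE]

  F_rec <- matrix(0, h$N, C)
  diag_rows <- vector("list", C)
  for (j in seq_len(C)) {
    sigma <- cfg$sigma %||% max(default_sigma(q, length(keep)),
                                cfg$sigma_rel * sqrt(sum(Y[, j]^2)))
    sol <- bpdn_solve(A, Y[, j], sigma = sigma, max_matvec = cfg$max_matvec,
                      opt_tol = cfg$opt_tol, bp_tol = cfg$bp_tol,
                      max_inner = cfg$max_inner)
    F_rec[, j] <- drop(dict$Psi %*% sol$coef) + h$means[j]
    diag_rows[[j]] <- data.frame(channel = j,
                                 residual_norm = sol$residual_norm,
                                 l1_norm = sol$l1_norm, matvec = sol$matvec,
                                 converged = sol$converged)
  }
  structure(list(F_rec = F_rec, diagnostics = do.call(rbind, diag_rows),
                 rows_kept = keep, rows_lost = M - length(keep)),
            class = "reconstructed_epoch")
}

#' @export
print.reconstructed_epoch <- function(x, ...) {
  cat(sprintf("<reconstructed_epoch> %d x %d, %d/%d measurement rows used\n",
              nrow(x$F_rec), ncol(x$F_rec), length(x$rows_kept),
              length(x$rows_kept) + x$rows_lost))
  invisible(x)
}

# Decode what survives a set of lost packets.  Received packets form
# contiguous runs; within each run, decoding starts at the first symbol
# whose encoded bits lie entirely inside the run (encoder bit positions
# give the alignment) and stops at the last such symbol.
decode_with_loss <- function(cz, cb, lost_packets) {
  pk <- cz$packets
  pos <- cz$meta$sym_bitpos                    # 0-based start bit per symbol
  n_sym <- cz$header$n_symbols
  ends <- c(pos[-1L], cz$header$payload_bits)  # end bit per symbol
  payload_bits <- PACKET_PAYLOAD * 8L
  received <- setdiff(pk$seq, lost_packets)
  codes <- integer(n_sym)
  sym_ok <- rep(FALSE, n_sym)
  if (length(received) == 0L) return(list(codes = codes, sym_ok = sym_ok))
  runs <- split(received, cumsum(c(1L, diff(received) != 1L)))
  for (run in runs) {
    bit_lo <- (run[1L] - 1L) * payload_bits
    bit_hi <- min(run[length(run)] * payload_bits, cz$header$payload_bits)
    inside <- which(pos >= bit_lo & ends <= bit_hi)
    if (length(inside) == 0L) next
    bytes <- do.call(c, pk$payloads[match(run, pk$seq)])
    bs <- list(bytes = bytes, nbits = length(run) * payload_bits)
    first <- inside[1L]
    decoded <- huffman_decode(bs, cb, length(inside),
                              start_bit = pos[first] - bit_lo)
    codes[inside] <- decoded
    sym_ok[inside] <- TRUE
  }
  list(codes = codes, sym_ok = sym_ok)
}
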