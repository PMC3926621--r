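#' Wavelet baseline codec
#'
#' The comparison codec: a JPEG2000-style scheme that computes the
#' Cohen-Daubechies-Feauveau 9/7 discrete wavelet transform of each raw
#' channel (lifting implementation, decomposition level 7 by default),
#' keeps only the largest-magnitude coefficients consistent with the
#' target compression ratio, and codes their positions (as a gap sequence)
#' and 12-bit quantized values with an adaptive arithmetic coder.  Unlike
#' the compressed-sensing path, this scheme is adaptive — it inspects the
#' signal to find its large coefficients — and concentrates the
#' computational load at the sensor.
#'
#' @name wavelet_baseline
NULL

# CDF 9/7 lifting constants (Daubechies & Sweldens factorization).
CDF97 <- list(a = -1.586134342, b = -0.05298011854,
              g = 0.8829110762, d = 0.4435068522, z = 1.149604398)

dwt97_step <- function(x) {
  n <- length(x)
  s <- x[seq(1L, n, 2L)]
  d <- x[seq(2L, n, 2L)]
  m <- length(s)
  d <- d + CDF97$a * (s + c(s[-1L], s[m]))
  s <- s + CDF97$b * (d + c(d[1L], d[-m]))
  d <- d + CDF97$g * (s + c(s[-1L], s[m]))
  s <- s + CDF97$d * (d + c(d[1L], d[-m]))
  list(s = s * CDF97$z, d = d / CDF97$z)
}

idwt97_step <- function(s, d) {
  m <- length(s)
  s <- s / CDF97$z
  d <- d * CDF97$z
  s <- s - CDF97$d * (d + c(d[1L], d[-m]))
  d <- d - CDF97$g * (s + c(s[-1L], s[m]))
  s <- s - CDF97$b * (d + c(d[1L], d[-m]))
  d <- d - CDF97$a * (s + c(s[-1L], s[m]))
  x <- numeric(2L * m)
  x[seq(1L, 2L * m, 2L)] <- s
  x[seq(2L, 2L * m, 2L)] <- d
  x
}

#' CDF 9/7 forward / inverse discrete wavelet transform
#'
#' Perfect-reconstruction lifting implementation with symmetric boundary
#' handling.  `dwt97_forward()` returns the coefficients as one vector in
#' the layout `[approximation, detail_L, detail_{L-1}, ..., detail_1]`
#' with attributes recording the level structure.
#'
#' @param x signal whose length is divisible by `2^level`.
#' @param level decomposition depth (default 7).
#' @return Numeric coefficient vector with attributes `level` and `n`.
#' @export
dwt97_forward <- function(x, level = 7L) {
  n <- length(x)
  if (n %% 2L^level != 0L)
    stop(sprintf("length %d not divisible by 2^%d", n, level))
  details <- vector("list", level)
  s <- as.numeric(x)
  for (l in seq_len(level)) {
    st <- dwt97_step(s)
    s <- st$s
    details[[l]] <- st$d
  }
  coeffs <- c(s, unlist(rev(details)))
  structure(coeffs, level = level, n = n)
}

#' @rdname dwt97_forward
#' @param coeffs output of `dwt97_forward()` (attributes intact, or pass
#'   `level` explicitly).
#' @export
dwt97_inverse <- function(coeffs, level = attr(coeffs, "level")) {
  n <- length(coeffs)
  n_app <- n / 2L^level
  s <- coeffs[seq_len(n_app)]
  off <- n_app
  for (l in rev(seq_len(level))) {
    d <- coeffs[(off + 1L):(off + length(s))]
    s <- idwt97_step(s, d)
    off <- off + length(d)
  }
  as.numeric(s)
}

#' Adaptive arithmetic encode / decode
#'
#' Order-0 adaptive model over the alphabet `0 .. alphabet-1`; no side
#' table is transmitted.  `arithmetic_decode(arithmetic_encode(x), n,
#' alphabet)` is an exact round trip.
#'
#' @param symbols integer vector in `0 .. alphabet-1`.
#' @param alphabet alphabet size.
#' @return `arithmetic_encode()`: a `bitstream` (raw bytes + bit count).
#' @export
arithmetic_encode <- function(symbols, alphabet) {
  if (length(symbols) == 0L)
    return(structure(list(bytes = raw(0), nbits = 0L), class = "bitstream"))
  r <- arith_encode_cpp(as.integer(symbols), as.integer(alphabet))
  structure(list(bytes = r$bytes, nbits = r$nbits), class = "bitstream")
}

#' @rdname arithmetic_encode
#' @param bits a `bitstream`.
#' @param n number of symbols to decode.
#' @export
arithmetic_decode <- function(bits, n, alphabet) {
  if (n == 0L) return(integer(0))
  arith_decode_cpp(bits$bytes, bits$nbits, as.integer(n), as.integer(alphabet))
}

# Encode one channel's kept coefficients: positions as an arithmetic-coded
# gap sequence, values 12-bit uniformly quantized over the kept range.
encode_channel_topk <- function(w, k, coef_bits, N) {
  ord <- order(-abs(w), seq_along(w))
  idx <- sort(ord[seq_len(k)])
  vals <- w[idx]
  hi <- max(abs(vals)) * (1 + 1e-9) + 1e-12
  q <- quantizer_spec(coef_bits, -hi, hi)
  codes <- quantize(vals, q)
  gaps <- diff(c(0L, idx)) - 1L
  gs <- arithmetic_encode(gaps, N)
  vs <- arithmetic_encode(codes, 2L^coef_bits)
  # per-channel header: k (16 bits) + range (32-bit float)
  list(k = k, idx = idx, hi = hi, gaps_stream = gs, vals_stream = vs,
       bits = 16L + 32L + gs$nbits + vs$nbits)
}

#' Keep the largest wavelet coefficients within a bit budget
#'
#' Selects the largest `k` coefficients by magnitude (ties broken by
#' index), with `k` found by searching the actual arithmetic-coded size
#' (gap-coded positions + quantized values + per-channel header) against
#' the budget `n * bits_per_sample / cr_target` implied by the target
#' compression ratio.
#'
#' @param coeffs coefficient vector from [dwt97_forward()].
#' @param cr_target target compression ratio (> 1).
#' @param coef_bits value quantizer width (default 12).
#' @param bits_per_sample raw amplitude width of the original signal.
#' @return List with `k`, kept `idx` and quantization range `hi`, the two
#'   coded streams, and `bits`, the total coded size.
#' @export
threshold_topk <- function(coeffs, cr_target, coef_bits = 12L,
                           bits_per_sample = 12L) {
  if (cr_target <= 1) stop("cr_target must exceed 1")
  N <- length(coeffs)
  budget <- N * bits_per_sample / cr_target
  k <- max(1L, min(N, floor(budget / (coef_bits + log2(N) + 3))))
  enc <- encode_channel_topk(coeffs, k, coef_bits, N)
  if (enc$bits <= budget) {
    while (k < N) {
      trial <- encode_channel_topk(coeffs, k + 1L, coef_bits, N)
      if (trial$bits > budget) break
      k <- k + 1L
      enc <- trial
    }
  } else {
    while (k > 1L && enc$bits > budget) {
      k <- k - 1L
      enc <- encode_channel_topk(coeffs, k, coef_bits, N)
    }
    if (enc$bits > budget)
      stop("target CR unachievable: even one coefficient exceeds the budget")
  }
  enc
}

#' Compress an epoch with the wavelet baseline
#'
#' Per channel: CDF 9/7 transform, then the largest `k` coefficients are
#' kept with `k` chosen (by search over the actual coded size) so the
#' arithmetic-coded payload meets the per-channel share of the target
#' compression ratio.  Ties in magnitude break by coefficient index.
#'
#' @param e `N x C` epoch matrix (raw, not demeaned).
#' @param target_cr target compression ratio (> 1).
#' @param level decomposition level (default 7).
#' @param coef_bits value quantizer width (default 12).
#' @param bits_per_sample raw amplitude width for the bit budget.
#' @return Object of class `wavelet_compressed_epoch` with per-channel
#'   coded streams, the shared packet sequence and the measured CR.
#' @export
wavelet_compress <- function(e, target_cr = 2, level = 7L, coef_bits = 12L,
                             bits_per_sample = 12L) {
  e <- as.matrix(e)
  N <- nrow(e); C <- ncol(e)
  if (target_cr <= 1) stop("target_cr must exceed 1")
  channels <- vector("list", C)
  for (j in seq_len(C)) {
    w <- dwt97_forward(e[, j], level)
    channels[[j]] <- threshold_topk(w, target_cr, coef_bits, bits_per_sample)
  }
  # one shared bitstream for packetization; record channel bit offsets
  ch_bits <- vapply(channels, function(x) x$bits, 0)
  all_bytes <- do.call(c, lapply(channels, function(ch)
    c(ch$gaps_stream$bytes, ch$vals_stream$bytes)))
  nbits_total <- sum(vapply(channels, function(ch)
    8 * (length(ch$gaps_stream$bytes) + length(ch$vals_stream$bytes)), 0))
  pk <- packetize(structure(list(bytes = all_bytes, nbits = nbits_total),
                            class = "bitstream"))
  payload_bits <- sum(ch_bits)
  structure(list(N = N, C = C, level = level, coef_bits = coef_bits,
                 channels = channels, packets = pk,
                 payload_bits = payload_bits,
                 cr_measured = compression_ratio(
                   raw_bits(N, C, bits_per_sample), payload_bits)),
            class = "wavelet_compressed_epoch")
}

#' @rdname wavelet_compress
#' @param wz a `wavelet_compressed_epoch`.
#' @param lost_packets lost packet sequence numbers; the coefficients
#'   whose coded bits map into lost packets are zeroed (a deliberately
#'   charitable loss model for the baseline — a real arithmetic decoder
#'   would lose everything after the first missing packet).
#' @export
wavelet_decompress <- function(wz, lost_packets = integer(0)) {
  N <- wz$N
  q_cache <- list()
  out <- matrix(0, N, wz$C)
  payload_bits <- PACKET_PAYLOAD * 8L
  lost_lo <- (lost_packets - 1L) * payload_bits
  lost_hi <- lost_packets * payload_bits
  bit_off <- 0
  for (j in seq_len(wz$C)) {
    ch <- wz$channels[[j]]
    gaps <- arithmetic_decode(ch$gaps_stream, ch$k, N)
    idx <- cumsum(gaps + 1L)
    q <- quantizer_spec(wz$coef_bits, -ch$hi, ch$hi)
    vals <- dequantize(arithmetic_decode(ch$vals_stream, ch$k, 2L^wz$coef_bits), q)
    ch_len <- 8 * (length(ch$gaps_stream$bytes) + length(ch$vals_stream$bytes))
    if (length(lost_packets) > 0L && ch$k > 0L) {
      # coefficient i occupies, nominally, the i-th share of the channel's bits
      pos <- bit_off + (seq_len(ch$k) - 0.5) / ch$k * ch_len
      hit <- vapply(pos, function(p) any(p >= lost_lo & p < lost_hi), NA)
      vals[hit] <- 0
    }
    w <- numeric(N)
    w[idx] <- vals
    attr(w, "level") <- wz$level
    out[, j] <- dwt97_inverse(w, wz$level)
    bit_off <- bit_off + ch_len
  }
  out
}
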