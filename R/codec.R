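#' Quantization, entropy coding and packetization
#'
#' After difference coding, the `M x C` block is vectorized in interleaved
#' (sample-major) order so every packet carries data from all channels,
#' uniformly quantized (15 bits by default, three bits of headroom over the
#' 12-bit raw range because the linear projections expand the signal
#' range), Huffman coded against an offline codebook, and split into
#' 127-byte packets of which 13 bytes are MAC overhead (114-byte payload).
#'
#' @name codec
NULL

#' Interleave / deinterleave a difference block
#'
#' `interleave()` stacks the transpose column-wise, producing
#' `[y1(1), y2(1), ..., yC(1), y1(2), ...]` so that consecutive symbols
#' cycle through channels (a lost packet then hits a few samples of every
#' channel rather than a burst of one channel).
#'
#' @param Yt `M x C` matrix.
#' @return Numeric vector of length `M*C`.
#' @export
interleave <- function(Yt) as.vector(t(as.matrix(Yt)))

#' @rdname interleave
#' @param v interleaved vector of length `M*C`.
#' @param C channel count.
#' @export
deinterleave <- function(v, C) {
  if (length(v) %% C != 0L) stop("length not divisible by channel count")
  t(matrix(v, nrow = C))
}

#' Uniform scalar quantizer specification
#'
#' Mid-rise quantizer mapping `[lo, hi)` onto codes `0 .. 2^bits - 1`.
#' The default range is +/- 2^14 (eight times the 12-bit raw amplitude
#' scale) at 15 bits, giving a unit step: measurement values keep the
#' granularity of the original integer samples.
#'
#' @param bits code width (>= 2, default 15).
#' @param lo,hi representable range endpoints in measurement units.
#' @return Object of class `quantizer_spec` with a `step` field.
#' @export
quantizer_spec <- function(bits = 15L, lo = -2^14, hi = 2^14) {
  bits <- as.integer(bits)
  if (bits < 2L) stop("bits must be at least 2")
  if (lo >= hi) stop("lo must be smaller than hi")
  structure(list(bits = bits, lo = lo, hi = hi,
                 step = (hi - lo) / 2^bits),
            class = "quantizer_spec")
}

#' Quantize / dequantize measurement values
#'
#' Out-of-range values are clipped to the end codes; the number of clipped
#' samples is recorded in the `clipped` attribute of the result.
#' `dequantize()` returns cell midpoints, so the round-trip error of
#' in-range values is at most `step/2`.
#'
#' @param v numeric vector.
#' @param q a [quantizer_spec()].
#' @return `quantize()`: integer code vector in `0 .. 2^bits - 1`.
#' @export
quantize <- function(v, q) {
  codes <- floor((as.numeric(v) - q$lo) / q$step)
  n_clip <- sum(codes < 0 | codes > 2^q$bits - 1)
  codes <- pmin(pmax(codes, 0), 2^q$bits - 1)
  structure(as.integer(codes), clipped = n_clip)
}

#' @rdname quantize
#' @param codes integer code vector.
#' @export
dequantize <- function(codes, q) {
  q$lo + (as.numeric(codes) + 0.5) * q$step
}

# Polynomial rolling hash over the codebook contents, for a stable id.
codebook_id <- function(symbols, lengths) {
  h <- 17
  for (x in c(symbols, lengths)) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

# Huffman code lengths by the two-queue method over sorted counts.
huffman_lengths <- function(counts) {
  n <- length(counts)
  if (n == 1L) return(1L)
  nn <- 2L * n - 1L
  w <- c(counts, rep(NA_real_, n - 1L))
  parent <- integer(nn)
  q1 <- seq_len(n)      # leaf queue, already sorted by caller
  q2 <- integer(0)      # internal-node queue (nondecreasing weights)
  h1 <- 1L; h2 <- 1L
  nxt <- n
  pop <- function() {
    # prefer the leaf queue on ties for determinism
    if (h1 <= length(q1) && (h2 > length(q2) || w[q1[h1]] <= w[q2[h2]])) {
      v <- q1[h1]; h1 <<- h1 + 1L
    } else {
      v <- q2[h2]; h2 <<- h2 + 1L
    }
    v
  }
  for (k in seq_len(n - 1L)) {
    a <- pop(); b <- pop()
    nxt <- nxt + 1L
    w[nxt] <- w[a] + w[b]
    parent[a] <- nxt; parent[b] <- nxt
    q2 <- c(q2, nxt)
  }
  depths <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; v <- i
    while (parent[v] != 0L) { v <- parent[v]; d <- d + 1L }
    depths[i] <- d
  }
  pmax(depths, 1L)
}

#' Build a canonical Huffman codebook from training codes
#'
#' Code lengths come from the observed code histogram; codes are assigned
#' canonically (sorted by length, then symbol value) so the codebook is
#' reproducible from the histogram alone.  An escape symbol is appended by
#' default: codes never seen in training are transmitted as the escape
#' code followed by the raw `bits`-bit value, so offline codebooks remain
#' complete over the whole quantizer domain.
#'
#' @param training_codes integer vector of quantizer codes.
#' @param bits quantizer code width (escape payload width).
#' @param escape include the escape symbol? Default `TRUE`.
#' @return Object of class `huffman_codebook` with fields `symbols`,
#'   `lengths` (canonical order), `bits`, `escape` (symbol id or `NA`)
#'   and `id`.
#' @export
build_huffman_codebook <- function(training_codes, bits = 15L, escape = TRUE) {
  if (length(training_codes) == 0L) stop("empty training sample")
  tb <- table(as.integer(training_codes))
  symbols <- as.integer(names(tb))
  counts <- as.numeric(tb)
  esc <- NA_integer_
  if (escape) {
    esc <- 2L^as.integer(bits)     # outside the code domain
    symbols <- c(symbols, esc)
    counts <- c(counts, 1)
  }
  ord <- order(counts, symbols)
  lens <- huffman_lengths(counts[ord])
  symbols <- symbols[ord]
  # canonical order: by (length, symbol)
  ord2 <- order(lens, symbols)
  symbols <- symbols[ord2]
  lens <- as.integer(lens[ord2])
  structure(list(symbols = symbols, lengths = lens, bits = as.integer(bits),
                 escape = esc, id = codebook_id(symbols, lens)),
            class = "huffman_codebook")
}

#' @export
print.huffman_codebook <- function(x, ...) {
  cat(sprintf("<huffman_codebook> %d symbols, %d-bit domain, id %s\n",
              length(x$symbols), x$bits, x$id))
  invisible(x)
}

#' Huffman encode / decode
#'
#' Bit-exact round trip: `huffman_decode(huffman_encode(x, cb), cb,
#' length(x))` recovers `x`, including codes routed through the escape
#' symbol.  The returned bitstream records the starting bit offset of
#' every symbol (used by the packet-loss simulation to resynchronize
#' decoding after a gap).
#'
#' @param codes integer code vector.
#' @param cb a [build_huffman_codebook()] result.
#' @return `huffman_encode()`: object of class `bitstream` with `bytes`
#'   (raw vector, big-endian bit order), `nbits` and `sym_bitpos`.
#' @export
huffman_encode <- function(codes, cb) {
  if (length(codes) == 0L) {
    return(structure(list(bytes = raw(0), nbits = 0L,
                          sym_bitpos = integer(0)), class = "bitstream"))
  }
  r <- huffman_encode_cpp(as.integer(codes), cb$symbols, cb$lengths,
                          ifelse(is.na(cb$escape), -1L, cb$escape), cb$bits)
  structure(list(bytes = r$bytes, nbits = r$nbits, sym_bitpos = r$sym_bitpos),
            class = "bitstream")
}

#' @rdname huffman_encode
#' @param bits a `bitstream` (or list with `bytes` and `nbits`).
#' @param n_symbols number of symbols to decode.
#' @param start_bit bit offset to start from (for post-loss resync).
#' @export
huffman_decode <- function(bits, cb, n_symbols, start_bit = 0) {
  if (n_symbols == 0L) return(integer(0))
  huffman_decode_cpp(bits$bytes, bits$nbits, start_bit, as.integer(n_symbols),
                     cb$symbols, cb$lengths,
                     ifelse(is.na(cb$escape), -1L, cb$escape), cb$bits)
}

PACKET_BYTES <- 127L
PACKET_OVERHEAD <- 13L
PACKET_PAYLOAD <- PACKET_BYTES - PACKET_OVERHEAD  # 114

#' Split a bitstream into fixed-size packets
#'
#' Packets carry 114 payload bytes (127-byte packets minus 13 bytes of MAC
#' overhead); the last packet is zero-padded and the true bit length is
#' kept so `depacketize()` is exact.
#'
#' @param bits a `bitstream`.
#' @return Object of class `packet_sequence`: `payloads` (list of raw
#'   114-byte vectors), `seq` numbers and `nbits`.
#' @export
packetize <- function(bits) {
  nbytes <- length(bits$bytes)
  n_pkt <- ceiling(nbytes / PACKET_PAYLOAD)
  payloads <- lapply(seq_len(n_pkt), function(k) {
    chunk <- bits$bytes[((k - 1L) * PACKET_PAYLOAD + 1L):min(k * PACKET_PAYLOAD, nbytes)]
    c(chunk, raw(PACKET_PAYLOAD - length(chunk)))
  })
  structure(list(payloads = payloads, seq = seq_len(n_pkt),
                 nbits = bits$nbits), class = "packet_sequence")
}

#' @rdname packetize
#' @param p a `packet_sequence`.
#' @export
depacketize <- function(p) {
  gaps <- packet_gaps(p)
  if (length(gaps) > 0L)
    stop(sprintf("missing packet(s): %s", paste(gaps, collapse = ", ")))
  bytes <- do.call(c, c(p$payloads, list(raw(0))))
  bytes <- bytes[seq_len(ceiling(p$nbits / 8))]
  structure(list(bytes = bytes, nbits = p$nbits, sym_bitpos = NULL),
            class = "bitstream")
}

#' @rdname packetize
#' @export
packet_gaps <- function(p) {
  n_expect <- if (length(p$seq) == 0L) 0L else max(p$seq)
  full <- ceiling(p$nbits / 8 / PACKET_PAYLOAD)
  setdiff(seq_len(max(n_expect, full)), p$seq)
}

# Bits charged for the self-describing epoch header: fixed fields
# (N, C, M, d, quantizer bits, seed, codebook id, payload length, threshold)
# plus 16-bit fixed-point channel means and 17-bit pair-list triples.
header_bits <- function(C) 184L + 33L * C

#' Codec configuration
#'
#' @param target_cr target compression ratio before entropy coding; sets
#'   `M = round(N / target_cr)` unless `M` is given.
#' @param d ones per sensing-matrix column.
#' @param seed sensing matrix seed (shared via the header).
#' @param quant a [quantizer_spec()].
#' @param codebook offline [build_huffman_codebook()]; when `NULL` the
#'   codebook is trained on the epoch being compressed.
#' @param pairs a precomputed [select_pairs()] schedule (the predictive
#'   protocol applies the schedule from the previous epoch); when `NULL`
#'   it is computed from the current epoch's measurements.
#' @param bits_per_sample raw amplitude width for CR accounting.
#' @param M measurement count override.
#' @return List of class `codec_config`.
#' @export
codec_config <- function(target_cr = 2, d = 8L, seed = 1L,
                         quant = quantizer_spec(), codebook = NULL,
                         pairs = NULL, bits_per_sample = 12L, M = NULL) {
  structure(list(target_cr = target_cr, d = as.integer(d),
                 seed = as.integer(seed), quant = quant, codebook = codebook,
                 pairs = pairs, bits_per_sample = as.integer(bits_per_sample),
                 M = if (!is.null(M)) as.integer(M)),
            class = "codec_config")
}

#' Compress one epoch (full sensor-side path)
#'
#' demean -> sparse binary projection -> difference coding -> interleave ->
#' quantize -> Huffman -> packetize.  The header makes the result fully
#' self-describing (dimensions, matrix seed, fixed-point channel means,
#' pair list, codebook id, payload bit length); header bits are charged
#' against the measured compression ratio.
#'
#' @param e `N x C` epoch matrix.
#' @param cfg a [codec_config()].
#' @return Object of class `compressed_epoch` with `header`, `packets`
#'   and `meta` (codebook, symbol bit positions, clip count, measured CR).
#' @export
compress_epoch <- function(e, cfg = codec_config()) {
  e <- as.matrix(e)
  N <- nrow(e); C <- ncol(e)
  M <- cfg$M %||% as.integer(round(N / cfg$target_cr))
  dm <- demean(e)
  # fixed-point means (1/8 resolution, 16-bit) so encoder and decoder agree
  means_fp <- unname(round(dm$means * 8) / 8)
  phi <- sparse_binary_matrix(M, N, cfg$d, cfg$seed)
  Y <- project_epoch(phi, dm)
  pairs <- cfg$pairs %||%
    select_pairs(correlation_matrix(Y), apply(Y, 2L, var))
  Yt <- apply_differences(Y, pairs)
  codes <- quantize(interleave(Yt), cfg$quant)
  cb <- cfg$codebook %||% build_huffman_codebook(codes, cfg$quant$bits)
  enc <- huffman_encode(codes, cb)
  pk <- packetize(enc)
  hdr <- list(N = N, C = C, M = M, d = cfg$d, seed = cfg$seed,
              bits = cfg$quant$bits, lo = cfg$quant$lo, hi = cfg$quant$hi,
              means = means_fp, pairs = pairs, codebook_id = cb$id,
              payload_bits = enc$nbits, n_symbols = length(codes),
              header_bits = header_bits(C))
  cr <- compression_ratio(raw_bits(N, C, cfg$bits_per_sample),
                          enc$nbits + header_bits(C))
  structure(list(header = hdr, packets = pk,
                 meta = list(codebook = cb, sym_bitpos = enc$sym_bitpos,
                             clipped = attr(codes, "clipped"),
                             cr_measured = cr)),
            class = "compressed_epoch")
}

#' @rdname compress_epoch
#' @param cz a `compressed_epoch`.
#' @export
decompress_header <- function(cz) cz$header

#' @export
print.compressed_epoch <- function(x, ...) {
  h <- x$header
  cat(sprintf(paste0("<compressed_epoch> N = %d, C = %d, M = %d, d = %d, ",
                     "%d packets, measured CR %.2f:1\n"),
              h$N, h$C, h$M, h$d, length(x$packets$payloads),
              x$meta$cr_measured))
  invisible(x)
}

#' Read/write the on-disk compressed format
#'
#' Binary layout: magic `EEGCS1`; little-endian integers `N, C, M, d,
#' bits, seed, n_symbols, payload_bits`; `lo, hi` as doubles; `C` means as
#' 32-bit fixed point (value * 8); `C` pair triples `(i, j, sign)`; the
#' codebook (count, symbols, lengths); then the packet payload bytes.
#'
#' @param cz a `compressed_epoch`.
#' @param path file path.
#' @export
write_compressed_epoch <- function(cz, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  h <- cz$header
  writeBin(charToRaw("EEGCS1"), con)
  writeBin(as.integer(c(h$N, h$C, h$M, h$d, h$bits, h$seed,
                        h$n_symbols, h$payload_bits)), con,
           size = 4L, endian = "little")
  writeBin(as.numeric(c(h$lo, h$hi)), con, endian = "little")
  writeBin(as.integer(round(h$means * 8)), con, size = 4L, endian = "little")
  writeBin(as.integer(rbind(h$pairs$i, h$pairs$j, h$pairs$sign)), con,
           size = 4L, endian = "little")
  cb <- cz$meta$codebook
  writeBin(length(cb$symbols), con, size = 4L, endian = "little")
  writeBin(as.integer(cb$symbols), con, size = 4L, endian = "little")
  writeBin(as.integer(cb$lengths), con, size = 4L, endian = "little")
  for (pl in cz$packets$payloads) writeBin(pl, con)
  invisible(path)
}

#' @rdname write_compressed_epoch
#' @export
read_compressed_epoch <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6L))
  if (magic != "EEGCS1") stop("corrupted header: bad magic")
  ints <- readBin(con, "integer", 8L, size = 4L, endian = "little")
  names(ints) <- c("N", "C", "M", "d", "bits", "seed", "n_symbols",
                   "payload_bits")
  rng <- readBin(con, "numeric", 2L, endian = "little")
  means <- readBin(con, "integer", ints["C"], size = 4L, endian = "little") / 8
  ptri <- readBin(con, "integer", 3L * ints["C"], size = 4L, endian = "little")
  ptri <- matrix(ptri, nrow = 3L)
  pairs <- structure(data.frame(i = ptri[1L, ], j = ptri[2L, ],
                                sign = ptri[3L, ]),
                     class = c("pair_list", "data.frame"))
  ncb <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  syms <- readBin(con, "integer", ncb, size = 4L, endian = "little")
  lens <- readBin(con, "integer", ncb, size = 4L, endian = "little")
  esc <- 2L^ints[["bits"]]
  cb <- structure(list(symbols = syms, lengths = lens,
                       bits = ints[["bits"]],
                       escape = if (esc %in% syms) esc else NA_integer_,
                       id = codebook_id(syms, lens)),
                  class = "huffman_codebook")
  n_pkt <- ceiling(ceiling(ints[["payload_bits"]] / 8) / PACKET_PAYLOAD)
  payloads <- lapply(seq_len(n_pkt), function(k) readBin(con, "raw", PACKET_PAYLOAD))
  pk <- structure(list(payloads = payloads, seq = seq_len(n_pkt),
                       nbits = ints[["payload_bits"]]),
                  class = "packet_sequence")
  hdr <- list(N = ints[["N"]], C = ints[["C"]], M = ints[["M"]],
              d = ints[["d"]], seed = ints[["seed"]], bits = ints[["bits"]],
              lo = rng[1L], hi = rng[2L], means = means, pairs = pairs,
              codebook_id = cb$id, payload_bits = ints[["payload_bits"]],
              n_symbols = ints[["n_symbols"]],
              header_bits = header_bits(ints[["C"]]))
  structure(list(header = hdr, packets = pk,
                 meta = list(codebook = cb, sym_bitpos = NULL,
                             clipped = NA_integer_,
                             cr_measured = compression_ratio(
                               raw_bits(hdr$N, hdr$C),
                               hdr$payload_bits + hdr$header_bits))),
            class = "compressed_epoch")
}

#' Train an offline Huffman codebook from a recording
#'
#' Runs the sensor path (projection, difference coding, quantization) over
#' the epochs of a training recording and builds the codebook from the
#' pooled code histogram, mirroring offline codebook generation before
#' deployment.
#'
#' @param rec an `eeg_recording` (training data, distinct from test data).
#' @param cfg a [codec_config()].
#' @param N epoch length.
#' @return A `huffman_codebook`.
#' @export
train_codebook <- function(rec, cfg = codec_config(), N = 512L) {
  eps <- epoch_stream(rec, N)
  M <- cfg$M %||% as.integer(round(N / cfg$target_cr))
  phi <- sparse_binary_matrix(M, N, cfg$d, cfg$seed)
  pooled <- unlist(lapply(eps, function(e) {
    dm <- demean(e)
    Y <- project_epoch(phi, dm)
    pairs <- select_pairs(correlation_matrix(Y), apply(Y, 2L, var))
    as.integer(quantize(interleave(apply_differences(Y, pairs)), cfg$quant))
  }))
  build_huffman_codebook(pooled, cfg$quant$bits)
}
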