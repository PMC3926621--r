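test_that("interleaving is sample-major and exactly invertible", {
  Yt <- cbind(c("a", "b"), c("c", "d"))
  expect_equal(interleave(Yt), c("a", "c", "b", "d"))
  one <- matrix(rnorm(7), 7, 1)
  expect_equal(interleave(one), as.numeric(one))
  Y <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(deinterleave(interleave(Y), 4), Y)
})

test_that("the uniform quantizer maps endpoints and bounds round-trip error", {
  q <- quantizer_spec(bits = 8, lo = -4, hi = 4)
  expect_equal(q$step, 8 / 256)
  expect_equal(as.integer(quantize(-4, q)), 0L)
  expect_equal(as.integer(quantize(4 - 1e-9, q)), 255L)
  # dense scan across the representable range
  x <- seq(-4, 4 - 1e-6, length.out = 5000)
  err <- abs(dequantize(quantize(x, q), q) - x)
  expect_lte(max(err), q$step / 2 + 1e-12)
  # clipping is counted
  codes <- quantize(c(-10, 0, 10), q)
  expect_equal(attr(codes, "clipped"), 2)
  expect_equal(as.integer(codes), c(0L, 128L, 255L))   # mid-rise: 0 -> 2^(bits-1)
  expect_error(quantizer_spec(8, 1, 1), "lo must be smaller")
  expect_equal(quantizer_spec()$bits, 15L)
})

test_that("huffman codebooks are canonical, deterministic and near-entropy", {
  cb <- build_huffman_codebook(c(1, 1, 1, 2, 2, 2), bits = 4, escape = FALSE)
  expect_equal(sort(cb$lengths), c(1L, 1L))       # two equal symbols: 1 bit
  cb1 <- build_huffman_codebook(rep(7, 10), bits = 4, escape = FALSE)
  expect_equal(cb1$lengths, 1L)                   # degenerate tree convention
  # deterministic given the histogram
  set.seed(4)
  x <- sample(0:15, 500, replace = TRUE, prob = dnorm(0:15, 8, 2))
  expect_identical(build_huffman_codebook(x, 4), build_huffman_codebook(x, 4))
  # mean code length within 1 bit of the empirical entropy
  tab <- table(x) / length(x)
  H <- -sum(tab * log2(tab))
  cb2 <- build_huffman_codebook(x, 4, escape = FALSE)
  len_of <- cb2$lengths[match(as.integer(names(tab)), cb2$symbols)]
  expect_lte(sum(tab * len_of), H + 1)
  expect_error(build_huffman_codebook(integer(0)), "empty")
})

test_that("huffman encode/decode round trips bit-exactly, escape included", {
  set.seed(5)
  for (rep in 1:20) {
    train <- as.integer(pmin(pmax(round(rnorm(300, 128, 20)), 0), 255))
    cb <- build_huffman_codebook(train, bits = 8)
    x <- as.integer(sample(0:255, 200, replace = TRUE))  # includes unseen
    bs <- huffman_encode(x, cb)
    expect_identical(huffman_decode(bs, cb, length(x)), x)
  }
  cb <- build_huffman_codebook(0:3, bits = 8)
  expect_equal(huffman_encode(integer(0), cb)$nbits, 0L)
  expect_identical(huffman_decode(huffman_encode(integer(0), cb), cb, 0L),
                   integer(0))
  # truncated stream errors with the symbol index reached
  x <- rep(0:3, 25)
  bs <- huffman_encode(x, cb)
  bs$nbits <- bs$nbits %/% 2
  bs$bytes <- bs$bytes[seq_len(ceiling(bs$nbits / 8))]
  expect_error(huffman_decode(bs, cb, length(x)), "truncated")
})

test_that("packetization chunks 114-byte payloads and is exact", {
  mk <- function(nbits) {
    structure(list(bytes = as.raw(sample(0:255, ceiling(nbits / 8), TRUE)),
                   nbits = nbits), class = "bitstream")
  }
  expect_length(packetize(mk(0))$payloads, 0L)
  p <- packetize(mk(2280))                        # 285 bytes -> 3 packets
  expect_length(p$payloads, 3L)
  expect_true(all(lengths(p$payloads) == 114L))
  set.seed(6)
  bs <- mk(9000)
  back <- depacketize(packetize(bs))
  expect_identical(back$bytes, bs$bytes)
  expect_identical(back$nbits, bs$nbits)
  # missing packets are reported
  p2 <- packetize(bs)
  p2$payloads <- p2$payloads[-2]; p2$seq <- p2$seq[-2]
  expect_equal(packet_gaps(p2), 2L)
  expect_error(depacketize(p2), "missing packet")
})

test_that("compress_epoch produces a self-describing header", {
  set.seed(7)
  scfg <- synth_config(C = 4, N = 256, n_epochs = 1, seed = 8)
  e <- epoch_stream(generate_recording(scfg), 256)[[1]]
  cz <- compress_epoch(e, codec_config(target_cr = 2, d = 8, seed = 31))
  h <- decompress_header(cz)
  expect_equal(h$N, 256L); expect_equal(h$C, 4L)
  expect_equal(h$M, 128L); expect_equal(h$d, 8L); expect_equal(h$seed, 31L)
  expect_equal(h$means, unname(round(colMeans(e) * 8) / 8), tolerance = 1e-12)
  expect_equal(nrow(h$pairs), 4L)
  expect_equal(h$payload_bits, cz$packets$nbits)
  # entropy coding beats the raw 15-bit budget on correlated channels
  expect_lt(h$payload_bits, h$M * h$C * 15)
})

test_that("measured CR does not increase with M", {
  scfg <- synth_config(C = 4, N = 256, n_epochs = 1, seed = 9)
  e <- epoch_stream(generate_recording(scfg), 256)[[1]]
  crs <- vapply(c(32L, 64L, 128L), function(M)
    compress_epoch(e, codec_config(M = M, seed = 2))$meta$cr_measured, 0)
  expect_true(all(diff(crs) < 0))
})

test_that("a zero-signal epoch compresses to a near-empty payload", {
  e <- matrix(0, 256, 3)
  expect_warning(cz <- compress_epoch(e, codec_config(target_cr = 4, seed = 1)),
                 "zero-variance")
  expect_lt(cz$header$payload_bits, 256 * 3)      # far below 15 bits/sample
  codes <- huffman_decode(depacketize(cz$packets), cz$meta$codebook,
                          cz$header$n_symbols)
  v <- dequantize(codes, quantizer_spec(cz$header$bits, cz$header$lo, cz$header$hi))
  expect_true(all(abs(v) <= cz$header$hi / 2^cz$header$bits))  # quantizer midpoint of 0
})

test_that("the on-disk compressed format round trips", {
  scfg <- synth_config(C = 3, N = 256, n_epochs = 1, seed = 10)
  e <- epoch_stream(generate_recording(scfg), 256)[[1]]
  cz <- compress_epoch(e, codec_config(target_cr = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".eegcs")
  write_compressed_epoch(cz, path)
  back <- read_compressed_epoch(path)
  expect_equal(back$header[c("N", "C", "M", "d", "seed", "bits", "n_symbols",
                             "payload_bits")],
               cz$header[c("N", "C", "M", "d", "seed", "bits", "n_symbols",
                           "payload_bits")])
  expect_equal(back$header$means, cz$header$means)
  expect_equal(back$header$pairs$i, cz$header$pairs$i)
  expect_identical(
    huffman_decode(depacketize(back$packets), back$meta$codebook,
                   back$header$n_symbols),
    huffman_decode(depacketize(cz$packets), cz$meta$codebook,
                   cz$header$n_symbols))
})

test_that("a predictive pair schedule from the previous epoch still inverts", {
  scfg <- synth_config(C = 5, N = 256, n_epochs = 2, seed = 11)
  eps <- epoch_stream(generate_recording(scfg), 256)
  phi <- sparse_binary_matrix(128, 256, 8, seed = 3)
  Y1 <- project_epoch(phi, demean(eps[[1]]))
  p1 <- select_pairs(correlation_matrix(Y1), apply(Y1, 2, var))
  cz <- compress_epoch(eps[[2]], codec_config(target_cr = 2, seed = 3, pairs = p1))
  expect_equal(cz$header$pairs$i, p1$i)
  Y2 <- project_epoch(phi, demean(eps[[2]]))
  expect_lt(max(abs(invert_differences(apply_differences(Y2, p1), p1) - Y2)),
            1e-9)
})
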