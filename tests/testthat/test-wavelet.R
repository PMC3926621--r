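test_that("CDF 9/7 forward/inverse is a perfect-reconstruction pair", {
  set.seed(41)
  for (case in list(c(512, 7), c(256, 5), c(64, 3))) {
    x <- rnorm(case[1], sd = 100)
    w <- dwt97_forward(x, case[2])
    expect_equal(dwt97_inverse(w), x, tolerance = 1e-9)
  }
  expect_error(dwt97_forward(rnorm(100), 7), "not divisible")
})

test_that("a constant signal concentrates in the coarsest band", {
  x <- rep(3, 512)
  w <- dwt97_forward(x, 7)
  n_app <- 512 / 2^7
  expect_gt(sum(w[seq_len(n_app)]^2) / sum(w^2), 1 - 1e-9)
})

test_that("adaptive arithmetic coding round trips exactly", {
  set.seed(42)
  for (alpha in c(4L, 64L, 1024L)) {
    x <- sample(0:(alpha - 1), 300, replace = TRUE)
    bs <- arithmetic_encode(x, alpha)
    expect_identical(arithmetic_decode(bs, length(x), alpha), x)
  }
  expect_equal(arithmetic_encode(integer(0), 16)$nbits, 0L)
  expect_identical(arithmetic_decode(arithmetic_encode(integer(0), 16), 0, 16),
                   integer(0))
  # a constant source costs far less than uniform coding
  x <- rep(7L, 2000)
  bs <- arithmetic_encode(x, 256)
  expect_lt(bs$nbits, 2000)                   # << 8 bits/symbol
  # truncation is detected
  y <- sample(0:255, 400, replace = TRUE)
  bs2 <- arithmetic_encode(y, 256)
  bs2$nbits <- bs2$nbits %/% 4
  bs2$bytes <- bs2$bytes[seq_len(ceiling(bs2$nbits / 8))]
  expect_error(arithmetic_decode(bs2, 400, 256), "truncated|corrupt")
})

test_that("top-k thresholding meets its bit budget and keeps the largest", {
  scfg <- synth_config(C = 2, N = 512, n_epochs = 1, seed = 43)
  e <- epoch_stream(generate_recording(scfg), 512)[[1]]
  for (cr in c(4, 2)) {
    wz <- wavelet_compress(e, target_cr = cr)
    expect_lte(wz$payload_bits, 512 * 2 * 12 / cr)  # coded size within budget
    expect_gte(wz$cr_measured, cr)
  }
  # the standalone selector keeps exactly the largest-magnitude entries
  w <- dwt97_forward(e[, 1], 7)
  enc <- threshold_topk(w, cr_target = 4)
  ord <- order(-abs(w), seq_along(w))
  expect_setequal(enc$idx, ord[seq_len(enc$k)])
  expect_lte(enc$bits, 512 * 12 / 4)
  expect_error(threshold_topk(w, cr_target = 1), "exceed 1")
  # an exactly wavelet-sparse signal with a budget that admits its support
  w0 <- numeric(512); w0[c(1, 2, 40, 200, 400)] <- c(500, -300, 200, 150, -100)
  attr(w0, "level") <- 7L
  x0 <- matrix(dwt97_inverse(w0, 7), ncol = 1)
  wz0 <- wavelet_compress(x0, target_cr = 8)
  x0_rec <- wavelet_decompress(wz0)
  expect_lt(nmse(x0[, 1], x0_rec[, 1]), 1e-4)       # 12-bit coefficient quantization
  expect_error(wavelet_compress(x0, target_cr = 1), "exceed 1")
})

test_that("near-lossless limit: generous budgets keep almost everything", {
  scfg <- synth_config(C = 1, N = 256, n_epochs = 1, seed = 44)
  e <- epoch_stream(generate_recording(scfg), 256)[[1]]
  wz <- wavelet_compress(e, target_cr = 1.05, level = 5)
  rec <- wavelet_decompress(wz)
  expect_lt(nmse(e[, 1], rec[, 1]), 1e-3)
})

test_that("lost packets zero the mapped coefficients without corrupting others", {
  scfg <- synth_config(C = 3, N = 512, n_epochs = 1, seed = 45)
  e <- epoch_stream(generate_recording(scfg), 512)[[1]]
  wz <- wavelet_compress(e, target_cr = 2)
  full <- wavelet_decompress(wz)
  n_pkt <- length(wz$packets$payloads)
  lost <- c(1L, n_pkt %/% 2L)
  part <- wavelet_decompress(wz, lost_packets = lost)
  m_full <- mean(sapply(1:3, function(j) nmse(e[, j], full[, j])))
  m_part <- mean(sapply(1:3, function(j) nmse(e[, j], part[, j])))
  expect_gt(m_part, m_full)                   # losing data hurts
  expect_lt(m_part, 1)                        # but does not destroy the epoch
  expect_identical(wavelet_decompress(wz, integer(0)), full)
})
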