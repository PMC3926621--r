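test_that("bpdn degenerate inputs return the zero solution", {
  A <- matrix(rnorm(40 * 80), 40, 80)
  z <- bpdn_solve(A, rep(0, 40))
  expect_equal(z$coef, rep(0, 80))
  expect_true(z$converged)
  y <- rnorm(40)
  big <- bpdn_solve(A, y, sigma = 2 * sqrt(sum(y^2)))
  expect_equal(big$coef, rep(0, 80))          # zero is feasible and l1-minimal
})

test_that("planted sparse coefficients are recovered at sigma = 0", {
  N <- 128
  dict <- gabor_dictionary(N)
  K <- ncol(dict$Psi)
  phi <- sparse_binary_matrix(64, N, 8, seed = 5)
  A <- as.matrix(as_sparse_Matrix(phi) %*% dict$Psi)
  set.seed(31)
  for (rep in 1:5) {
    sup <- integer(0)
    while (length(sup) < 5) {
      cand <- sample.int(K, 1)
      if (length(sup) == 0 ||
          max(abs(crossprod(dict$Psi[, sup, drop = FALSE],
                            dict$Psi[, cand]))) <= 0.5)
        sup <- c(sup, cand)
    }
    c0 <- numeric(K); c0[sup] <- rnorm(5) + sign(rnorm(5))
    y <- drop(A %*% c0)
    sol <- bpdn_solve(A, y, sigma = 0)
    expect_lt(sqrt(sum((sol$coef - c0)^2)) / sqrt(sum(c0^2)), 1e-3)
  }
})

test_that("with M = N and an invertible dense matrix, reconstruction matches
           direct inversion", {
  N <- 64
  dict <- gabor_dictionary(N)
  set.seed(32)
  Phi <- diag(N) + matrix(rnorm(N * N, sd = 0.05), N, N)
  f <- drop(dict$Psi[, 40] * 2 + dict$Psi[, 80])
  y <- drop(Phi %*% f)
  A <- Phi %*% dict$Psi
  sol <- bpdn_solve(A, y, sigma = 0, bp_tol = 1e-9)
  f_hat <- drop(dict$Psi %*% sol$coef)
  f_ls <- drop(solve(Phi, y))                 # least-squares/direct inverse
  expect_lt(sqrt(sum((f_hat - f_ls)^2)) / sqrt(sum(f_ls^2)), 1e-6)
})

test_that("the quantization sigma rule is the aggregated uniform-error RMS", {
  q <- quantizer_spec(15, -2^14, 2^14)
  expect_equal(default_sigma(q, 144), q$step * 12 / sqrt(12))
})

test_that("quantization-calibrated sigma is no worse than sigma = 0", {
  N <- 128
  dict <- gabor_dictionary(N)
  K <- ncol(dict$Psi)
  q <- quantizer_spec(12, -2^8, 2^8)
  phi <- sparse_binary_matrix(64, N, 8, seed = 6)
  A <- as.matrix(as_sparse_Matrix(phi) %*% dict$Psi)
  set.seed(33)
  ratio <- replicate(5, {
    sup <- sample(K, 4)
    c0 <- numeric(K); c0[sup] <- rnorm(4) * 5
    f <- drop(dict$Psi %*% c0)
    y_q <- dequantize(quantize(drop(A %*% c0), q), q)
    f0 <- drop(dict$Psi %*% bpdn_solve(A, y_q, sigma = 0)$coef)
    fq <- drop(dict$Psi %*% bpdn_solve(A, y_q,
                                       sigma = default_sigma(q, 64))$coef)
    nmse(f, fq) / max(nmse(f, f0), 1e-12)
  })
  expect_lte(mean(ratio), 1 + 1e-6)
})

test_that("all-constant channels reconstruct exactly through the full path", {
  e <- cbind(rep(120, 256), rep(-40, 256))
  expect_warning(cz <- compress_epoch(e, codec_config(target_cr = 4, seed = 9)),
                 "zero-variance")
  dict <- gabor_dictionary(256)
  rc <- reconstruct_epoch(cz, dict)
  # the mid-rise quantizer reproduces the zero residue as +/- step/2, so
  # recovery is exact up to that granularity
  expect_lt(max(abs(rc$F_rec - e)), 2 * quantizer_spec()$step)
})

test_that("a planted Gabor-sparse epoch survives the full digital path", {
  N <- 512
  dict <- gabor_dictionary(N)
  K <- ncol(dict$Psi)
  set.seed(34)
  mk_channel <- function() {
    sup <- integer(0)
    while (length(sup) < 8) {
      cand <- sample.int(K - 1, 1)            # exclude the DC atom
      if (length(sup) == 0 ||
          max(abs(crossprod(dict$Psi[, sup, drop = FALSE],
                            dict$Psi[, cand]))) <= 0.5)
        sup <- c(sup, cand)
    }
    drop(dict$Psi[, sup] %*% (rnorm(8) * 300 + 100 * sign(rnorm(8))))
  }
  e <- round(cbind(mk_channel(), mk_channel()))
  cz <- compress_epoch(e, codec_config(target_cr = 2, seed = 12))
  rc <- reconstruct_epoch(cz, dict, recon_config(sigma_rel = 0))
  for (j in 1:2) expect_lt(nmse(e[, j], rc$F_rec[, j]), 1e-3)
})

test_that("header corruption and codebook mismatch are caught", {
  scfg <- synth_config(C = 2, N = 256, n_epochs = 1, seed = 13)
  e <- epoch_stream(generate_recording(scfg), 256)[[1]]
  cz <- compress_epoch(e, codec_config(target_cr = 2, seed = 3))
  dict <- gabor_dictionary(256)
  bad <- cz; bad$header$N <- NULL
  expect_error(reconstruct_epoch(bad, dict), "corrupted header")
  other <- build_huffman_codebook(0:100, bits = 15)
  expect_error(reconstruct_epoch(cz, dict, codebook = other), "codebook id")
  expect_error(reconstruct_epoch(cz, gabor_dictionary(128)),
               "does not match")
})
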