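test_that("the grid-spacing constant alpha follows its closed form", {
  expect_equal(gabor_alpha(1), 0)
  expect_equal(gabor_alpha(2), 0.5 * log(0.5 * (2 + 0.5)))  # ~0.11157
  expect_equal(gabor_alpha(2), gabor_alpha(1 / 2))          # B <-> 1/B symmetry
  expect_error(gabor_alpha(0), "positive")
})

test_that("gabor atoms are unit norm, zero at center, odd about it", {
  g <- gabor_atom(n0 = 64, f0 = 0.1, s = 8, N = 128)
  expect_equal(sqrt(sum(g^2)), 1)
  expect_equal(g[65], 0)                     # sine vanishes at n0 (0-based 64)
  for (t in 1:20) expect_equal(g[65 + t], -g[65 - t], tolerance = 1e-12)
  expect_error(gabor_atom(10, 0.7, 4, 64), "f0")
  expect_error(gabor_atom(10, 0.1, -1, 64), "spread")
})

test_that("the dictionary is a redundant unit-norm frame on a dyadic scale set", {
  dict <- gabor_dictionary(64)
  K <- ncol(dict$Psi)
  expect_gte(K, 64)                          # redundancy
  expect_equal(apply(dict$Psi, 2, function(g) sqrt(sum(g^2))),
               rep(1, K), tolerance = 1e-12)
  s <- unique(dict$params$s[!is.na(dict$params$s)])
  expect_true(all(s %in% 2^(1:6)))           # B^1 .. B^log2(N)
  expect_true(any(is.na(dict$params$s)))     # DC atom present
  expect_lte(K, 16 * 64 + 1)
})

test_that("the frame spans the signal space", {
  dict <- gabor_dictionary(64)
  set.seed(21)
  x <- rnorm(64)
  cc <- qr.coef(qr(dict$Psi), x)
  cc[is.na(cc)] <- 0
  resid <- x - drop(dict$Psi %*% cc)
  expect_lt(sum(resid^2) / sum(x^2), 1e-6)
})

test_that("synthetic epochs are compressible: N/8 greedy atoms carry >=90% energy", {
  scfg <- synth_config(C = 4, N = 512, n_epochs = 2, seed = 22)
  eps <- epoch_stream(generate_recording(scfg), 512)
  dict <- gabor_dictionary(512)
  frac <- unlist(lapply(eps, function(e) {
    dm <- demean(e)
    vapply(seq_len(ncol(e)), function(j)
      matching_pursuit(dm$Ftilde[, j], dict, 64)$energy_captured, 0)
  }))
  expect_gte(mean(frac), 0.90)
})

test_that("a single interior atom is recovered from N/4 measurements", {
  N <- 128
  dict <- gabor_dictionary(N)
  K <- ncol(dict$Psi)
  interior <- which(!is.na(dict$params$s) & dict$params$s <= 16 &
                    dict$params$n0 > 32 & dict$params$n0 < 96)
  set.seed(23)
  k0 <- sample(interior, 1)
  phi <- sparse_binary_matrix(N / 4, N, 8, seed = 2)
  A <- as.matrix(as_sparse_Matrix(phi) %*% dict$Psi)
  y <- drop(A[, k0] * 3.2)
  sol <- bpdn_solve(A, y, sigma = 0)
  c0 <- numeric(K); c0[k0] <- 3.2
  expect_lt(sqrt(sum((sol$coef - c0)^2)) / 3.2, 1e-3)
})

test_that("matching pursuit reproduces an exactly sparse signal", {
  dict <- gabor_dictionary(64)
  set.seed(24)
  sel <- sample(ncol(dict$Psi), 3)
  x <- drop(dict$Psi[, sel] %*% c(2, -1, 0.5))
  mp <- matching_pursuit(x, dict, 25)
  expect_gt(mp$energy_captured, 0.999)
})
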