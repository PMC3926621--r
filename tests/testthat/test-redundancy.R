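test_that("measurement correlations match a textbook Pearson computation", {
  Y <- cbind(c(1, 2, 3), c(1, 2, 4))
  R <- correlation_matrix(Y)
  pearson <- function(a, b) {
    n <- length(a)
    cv <- sum((a - mean(a)) * (b - mean(b))) / (n - 1)
    cv / (sqrt(sum((a - mean(a))^2) / (n - 1)) *
          sqrt(sum((b - mean(b))^2) / (n - 1)))
  }
  expect_equal(R[1, 2], pearson(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(diag(R), c(1, 1), ignore_attr = TRUE)

  y1 <- rnorm(20)
  expect_equal(correlation_matrix(cbind(y1, y1))[1, 2], 1)
  expect_equal(correlation_matrix(cbind(y1, -y1))[1, 2], -1)

  expect_warning(Rz <- correlation_matrix(cbind(y1, rep(2, 20))),
                 "zero-variance")
  expect_equal(Rz[1, 2], 0)
  expect_equal(diag(Rz), c(1, 1), ignore_attr = TRUE)
})

test_that("greedy pair selection matches a brute-force re-find-max oracle", {
  # hand-built 3-channel case
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.99
  R[1, 3] <- R[3, 1] <- 0.70
  R[2, 3] <- R[3, 2] <- 0.65
  v <- c(3, 2, 1)
  p <- select_pairs(R, v, T = 0.6)
  expect_equal(p$i[1], 1L); expect_equal(p$j[1], 2L)
  orc <- oracle_select_pairs(R, v, T = 0.6)
  expect_equal(p$i, orc$i)
  expect_equal(p$j, orc$j)
  expect_equal(p$sign, orc$sign)

  # random correlation structures, C up to 8
  set.seed(7)
  for (rep in 1:20) {
    C <- sample(2:8, 1)
    Y <- make_correlated_block(30, C, rho = runif(1, 0.3, 0.98), seed = rep)
    R <- correlation_matrix(Y)
    v <- apply(Y, 2, var)
    p <- select_pairs(R, v)
    orc <- oracle_select_pairs(R, v)
    expect_equal(p$i, orc$i)
    expect_equal(p$j, orc$j)
    expect_equal(p$sign, orc$sign)
  }
})

test_that("pair selection handles the degenerate and threshold cases", {
  expect_equal(select_pairs(matrix(1, 1, 1), 5)$j, 0L)     # C=1 singleton
  # all correlations below threshold: only singletons, lowest variance first
  R <- diag(3); R[upper.tri(R)] <- 0.1; R[lower.tri(R)] <- 0.1
  p <- select_pairs(R, c(5, 1, 3), T = 0.6)
  expect_true(all(p$j == 0L))
  expect_equal(p$i, c(2L, 3L, 1L))
  # deterministic given R and variances
  Y <- make_correlated_block(25, 5, seed = 3)
  R <- correlation_matrix(Y); v <- apply(Y, 2, var)
  expect_identical(select_pairs(R, v), select_pairs(R, v))
})

test_that("the signed incidence system always has full rank", {
  set.seed(11)
  for (rep in 1:30) {
    C <- sample(2:8, 1)
    Y <- make_correlated_block(20, C, rho = runif(1, 0.2, 0.99), seed = rep)
    p <- select_pairs(correlation_matrix(Y), apply(Y, 2, var))
    A <- pair_incidence(p, C)
    expect_true(abs(det(A)) > 1e-8)              # exact full-rank check
  }
})

test_that("difference coding is exactly invertible", {
  # hand case: back-substitution
  p <- structure(data.frame(i = c(1L, 2L), j = c(2L, 0L), sign = c(1, 1)),
                 class = c("pair_list", "data.frame"))
  a <- rnorm(6); b <- rnorm(6)
  Yt <- apply_differences(cbind(a, b), p)
  expect_equal(Yt[, 1], a - b)
  expect_equal(Yt[, 2], b)
  expect_equal(invert_differences(Yt, p), cbind(a, b), ignore_attr = TRUE)

  # identical channels paired -> zero difference column
  pz <- select_pairs(correlation_matrix(cbind(a, a + 1e-14)), c(1, 1))
  Yz <- apply_differences(cbind(a, a), pz)
  expect_true(any(apply(Yz, 2, function(col) all(abs(col) < 1e-10))))

  # negative correlation flips the sign into an addition
  pn <- select_pairs(correlation_matrix(cbind(a, -a + 1e-12)), c(1, 1))
  k <- which(pn$j > 0)[1]
  expect_equal(pn$sign[k], -1)
  Yn <- apply_differences(cbind(a, -a), pn)
  expect_true(all(abs(Yn[, k]) < 1e-10))         # y_i + y_j cancels here

  # all-singleton schedule is the identity
  ps <- structure(data.frame(i = 1:3, j = rep(0L, 3), sign = rep(1, 3)),
                  class = c("pair_list", "data.frame"))
  Y <- matrix(rnorm(12), 4, 3)
  expect_equal(apply_differences(Y, ps), Y, ignore_attr = TRUE)
  expect_equal(invert_differences(Y, ps), Y, ignore_attr = TRUE)
})

test_that("apply/invert round trips exactly on random blocks, C in 2..21", {
  set.seed(13)
  for (rep in 1:50) {
    C <- sample(2:21, 1)
    Y <- make_correlated_block(24, C, rho = runif(1, 0.4, 0.99), seed = 100 + rep)
    p <- select_pairs(correlation_matrix(Y), apply(Y, 2, var))
    back <- invert_differences(apply_differences(Y, p), p)
    expect_lt(max(abs(back - Y)), 1e-10)
  }
})

test_that("difference columns have smaller variance on correlated channels", {
  # the distribution-narrowing property that makes differences cheap to code
  set.seed(17)
  wins <- 0L; total <- 0L
  for (rep in 1:100) {
    Y <- make_correlated_block(32, 4, rho = 0.9, seed = 200 + rep)
    p <- select_pairs(correlation_matrix(Y), apply(Y, 2, var))
    Yt <- apply_differences(Y, p)
    for (k in which(p$j > 0)) {
      total <- total + 1L
      if (var(Yt[, k]) < var(Y[, p$i[k]])) wins <- wins + 1L
    }
  }
  expect_gt(total, 100)
  expect_gt(wins / total, 0.99)
})

test_that("pair schedules are stable across epochs of stationary data", {
  scfg <- synth_config(C = 6, N = 256, n_epochs = 12, seed = 5)
  rec <- generate_recording(scfg)
  eps <- epoch_stream(rec, 256)
  phi <- sparse_binary_matrix(128, 256, 8, seed = 1)
  plists <- lapply(eps, function(e) {
    Y <- project_epoch(phi, demean(e))
    p <- select_pairs(correlation_matrix(Y), apply(Y, 2, var))
    p <- p[p$j > 0, ]                # the differenced pairs; singleton
    paste(sort(paste(p$i, p$j, p$sign)), collapse = ";")  # fill is variance-ranked
  })
  same <- mean(vapply(seq_len(length(plists) - 1),
                      function(k) plists[[k]] == plists[[k + 1]], NA))
  expect_gte(same, 0.8)
})

test_that("a corrupted pair list is reported as singular", {
  p <- structure(data.frame(i = c(1L, 1L), j = c(2L, 2L), sign = c(1, 1)),
                 class = c("pair_list", "data.frame"))
  expect_error(invert_differences(matrix(rnorm(8), 4, 2), p), "singular")
})
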