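# Shared fixtures, built in code.

# A block of highly correlated measurement columns: one base vector plus
# small channel-specific perturbations (pairwise r close to 1).
make_correlated_block <- function(M, C, rho = 0.95, seed = 1) {
  eegcs:::with_local_seed(seed, {
    base <- rnorm(M)
    sapply(seq_len(C), function(j)
      sqrt(rho) * base + sqrt(1 - rho) * rnorm(M))
  })
}

# Brute-force greedy pair selection: literally re-find the largest |R|
# entry each round, independent of the package's sorted-scan shortcut.
oracle_select_pairs <- function(R, variances, T = 0.6, tol = 1e-10) {
  C <- nrow(R)
  pool <- which(upper.tri(R), arr.ind = TRUE)
  pool <- data.frame(i = pool[, 1], j = pool[, 2])
  pool$r <- R[cbind(pool$i, pool$j)]
  rows <- matrix(0, 0, C)
  entries <- data.frame(i = integer(0), j = integer(0), sign = numeric(0))
  is_indep <- function(row) {
    qr(rbind(rows, row))$rank > nrow(rows)
  }
  while (nrow(entries) < C && nrow(pool) > 0) {
    ord <- order(-abs(pool$r), pool$i, pool$j)
    best <- pool[ord[1], ]
    pool <- pool[-ord[1], , drop = FALSE]
    if (abs(best$r) < T) break
    s <- if (best$r >= 0) 1 else -1
    row <- numeric(C); row[best$i] <- 1; row[best$j] <- -s
    if (is_indep(row)) {
      rows <- rbind(rows, row)
      entries <- rbind(entries, data.frame(i = best$i, j = best$j, sign = s))
    }
  }
  for (ch in order(variances, seq_len(C))) {
    if (nrow(entries) >= C) break
    row <- numeric(C); row[ch] <- 1
    if (is_indep(row)) {
      rows <- rbind(rows, row)
      entries <- rbind(entries, data.frame(i = ch, j = 0L, sign = 1))
    }
  }
  entries
}

# Write a minimal single-rate EDF file (16-bit LE samples) for reader tests.
write_synthetic_edf <- function(path, samples, fs = 128) {
  ns <- ncol(samples)
  n_per_rec <- fs
  n_records <- nrow(samples) %/% n_per_rec
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- sprintf(paste0("%-", w, "s"), as.character(x))
    writeBin(charToRaw(substr(s, 1, w)), con)
  }
  pad("0", 8); pad("synthetic patient", 80); pad("synthetic rec", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256 + 256 * ns, 8); pad("", 44)
  pad(n_records, 8); pad("1", 8); pad(ns, 4)
  for (i in seq_len(ns)) pad(paste0("ch", i), 16)
  for (i in seq_len(ns)) pad("synthetic", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad("-2048", 8)    # physical min
  for (i in seq_len(ns)) pad("2047", 8)     # physical max
  for (i in seq_len(ns)) pad("-2048", 8)    # digital min
  for (i in seq_len(ns)) pad("2047", 8)     # digital max
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(n_per_rec, 8)
  for (i in seq_len(ns)) pad("", 32)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      x <- samples[(r - 1) * n_per_rec + seq_len(n_per_rec), s]
      writeBin(as.integer(x), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
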