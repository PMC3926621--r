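#' Gabor sparsifying dictionary
#'
#' EEG epochs are compressible in a redundant frame of Gabor atoms:
#' unit-norm, sinusoidally-modulated Gaussian windows
#' `g(n) = K * exp(-(n - n0)^2 / (2 s^2)) * sin(2 pi f0 (n - n0))`
#' parameterized by center time `n0` (samples), center frequency `f0`
#' (cycles/sample) and spread `s` (samples).  Spreads follow a dyadic
#' scale; per spread the time grid step is proportional to `s` and the
#' frequency grid step inversely proportional to it, so the atoms tile the
#' time-frequency plane at roughly constant mutual distance.  The
#' dictionary is used only at the server during reconstruction.
#'
#' @name gabor
NULL

#' Discretization constant for the Gabor grids
#'
#' `alpha(B) = 0.5 * ln(0.5 * (B + 1/B))`, a function of the dyadic base
#' `B` controlling the spacing of the atom grid; symmetric in `B <-> 1/B`
#' and zero at `B = 1`.
#'
#' @param B dyadic base (> 0; default 2).
#' @return Scalar.
#' @export
gabor_alpha <- function(B = 2) {
  if (B <= 0) stop("B must be positive")
  0.5 * log(0.5 * (B + 1 / B))
}

#' Evaluate one unit-norm Gabor atom on `0 .. N-1`
#'
#' @param n0 center time in samples.
#' @param f0 center frequency in cycles/sample, `0 < f0 <= 0.5`.
#' @param s spread in samples (> 0).
#' @param N epoch length.
#' @return Length-`N` unit-norm vector.
#' @export
gabor_atom <- function(n0, f0, s, N) {
  if (s <= 0) stop("spread must be positive")
  if (f0 <= 0 || f0 > 0.5) stop("f0 must be in (0, 0.5]")
  n <- seq_len(N) - 1
  g <- exp(-(n - n0)^2 / (2 * s^2)) * sin(2 * pi * f0 * (n - n0))
  nrm <- sqrt(sum(g^2))
  if (nrm < 1e-10) stop("zero-energy atom for these parameters")
  g / nrm
}

# cache dictionaries per parameter set: tests and experiments rebuild the
# same dictionary many times and construction is the expensive part.
.dict_cache <- new.env(parent = emptyenv())

# Greedy near-duplicate removal: scan columns in order, keep a column only
# if its absolute inner product with every kept column stays below thr.
# Blocked matrix products keep this a one-time cost of a few seconds.
dedup_columns <- function(Psi, thr) {
  K <- ncol(Psi)
  kept <- logical(K)
  kept_idx <- integer(0)
  block <- 512L
  for (start in seq(1L, K, by = block)) {
    idx <- start:min(start + block - 1L, K)
    G_prev <- if (length(kept_idx) > 0L)
      abs(crossprod(Psi[, kept_idx, drop = FALSE], Psi[, idx, drop = FALSE]))
    else matrix(0, 0L, length(idx))
    G_self <- abs(crossprod(Psi[, idx, drop = FALSE]))
    ok_prev <- if (nrow(G_prev) > 0L) apply(G_prev, 2L, max) < thr
               else rep(TRUE, length(idx))
    sel <- logical(length(idx))
    for (k in seq_along(idx)) {
      if (!ok_prev[k]) next
      if (any(sel) && max(G_self[sel, k]) >= thr) next
      sel[k] <- TRUE
    }
    kept[idx[sel]] <- TRUE
    kept_idx <- which(kept)
  }
  kept
}

#' Build the redundant Gabor dictionary
#'
#' Spreads `s = B, B^2, ..., <= N`.  Per spread, center times step by
#' `dn0 = c_t * s` (floored at 1 sample) and center frequencies by
#' `df0 = c_f / (s * N)` (floored at `1/N`), with
#' `c_t = 2 alpha / pi` and `c_f = 8 pi alpha` by default.  Atoms are
#' truncated at the epoch boundary and renormalized; near-zero-energy
#' atoms are dropped.  A constant (DC) atom is appended.  If the grid
#' exceeds `cap` atoms, both increments are scaled up proportionally
#' until it fits.
#'
#' @param N epoch length (>= 8).
#' @param B dyadic base for the spread scale (default 2).
#' @param c_t,c_f grid constants (see above).
#' @param cap atom-count cap (default `16 * N`).
#' @param dedup_coherence atoms whose absolute inner product with an
#'   already-kept atom exceeds this are dropped (default 0.99).  Large
#'   spreads produce quasi-sinusoidal atoms that nearly duplicate one
#'   another across time shifts and scales; such near-dependencies make
#'   sparse representations non-identifiable and slow the solver without
#'   enlarging the span.  Set to 1 to disable.
#' @return Object of class `gabor_dictionary`: `Psi` (`N x K`, unit-norm
#'   columns), `params` (data frame of `n0`, `f0`, `s`; `NA` row for the
#'   DC atom) and the build parameters.
#' @export
gabor_dictionary <- function(N, B = 2,
                             c_t = 2 * gabor_alpha(B) / pi,
                             c_f = 8 * pi * gabor_alpha(B),
                             cap = 16L * N, dedup_coherence = 0.99) {
  if (N < 8L) stop("N must be at least 8")
  key <- paste(N, B, signif(c_t, 12), signif(c_f, 12), cap,
               dedup_coherence, sep = "|")
  if (!is.null(.dict_cache[[key]])) return(.dict_cache[[key]])

  scales <- B^seq_len(floor(log(N, B)))
  grid_for <- function(gamma) {
    do.call(rbind, lapply(scales, function(s) {
      dn0 <- max(1, gamma * c_t * s)
      df0 <- max(1 / N, gamma * c_f / (s * N))
      n0 <- seq(0, N - 1, by = dn0)
      f0 <- seq(df0, 0.5, by = df0)
      if (length(f0) == 0L) return(NULL)
      expand.grid(n0 = n0, f0 = f0, s = s)
    }))
  }
  gamma <- 1
  grid <- grid_for(gamma)
  while (nrow(grid) + 1L > cap) {
    gamma <- gamma * sqrt((nrow(grid) + 1) / cap) * 1.02
    grid <- grid_for(gamma)
    if (nrow(grid) < length(scales)) stop("cap too small to cover the scales")
  }

  n <- seq_len(N) - 1
  Psi <- matrix(0, N, nrow(grid))
  keep <- logical(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- exp(-(n - grid$n0[k])^2 / (2 * grid$s[k]^2)) *
      sin(2 * pi * grid$f0[k] * (n - grid$n0[k]))
    nrm <- sqrt(sum(g^2))
    if (nrm >= 1e-8) {
      Psi[, k] <- g / nrm
      keep[k] <- TRUE
    }
  }
  Psi <- Psi[, keep, drop = FALSE]
  grid <- grid[keep, , drop = FALSE]
  if (dedup_coherence < 1) {
    sel <- dedup_columns(Psi, dedup_coherence)
    Psi <- Psi[, sel, drop = FALSE]
    grid <- grid[sel, , drop = FALSE]
  }
  Psi <- cbind(Psi, rep(1 / sqrt(N), N))                 # DC atom
  params <- rbind(grid, data.frame(n0 = NA, f0 = NA, s = NA))
  if (ncol(Psi) < N)
    stop("dictionary is not redundant (K < N); increase cap or adjust grid")
  out <- structure(list(Psi = Psi, params = params, N = N, B = B,
                        c_t = c_t, c_f = c_f, cap = cap, gamma = gamma),
                   class = "gabor_dictionary")
  .dict_cache[[key]] <- out
  out
}

#' @export
print.gabor_dictionary <- function(x, ...) {
  cat(sprintf("<gabor_dictionary> N = %d, K = %d atoms, scales %s\n",
              x$N, ncol(x$Psi),
              paste(unique(x$params$s[!is.na(x$params$s)]), collapse = ",")))
  invisible(x)
}

#' Greedy matching pursuit (test oracle and compressibility probe)
#'
#' Iteratively selects the atom with the largest absolute inner product
#' with the residual.  Used to measure Gabor-domain compressibility of a
#' signal and as an independent greedy baseline for the convex solver; not
#' part of the production path.
#'
#' @param x length-`N` signal.
#' @param dict a `gabor_dictionary` (or `N x K` matrix).
#' @param n_atoms number of greedy selections.
#' @return List with `coef` (sparse coefficient vector, length `K`),
#'   `approx` (the reconstruction) and `energy_captured` (fraction of
#'   `||x||^2`).
#' @export
matching_pursuit <- function(x, dict, n_atoms) {
  Psi <- if (inherits(dict, "gabor_dictionary")) dict$Psi else dict
  r <- as.numeric(x)
  coef <- numeric(ncol(Psi))
  for (it in seq_len(n_atoms)) {
    ip <- drop(crossprod(Psi, r))
    k <- which.max(abs(ip))
    coef[k] <- coef[k] + ip[k]
    r <- r - ip[k] * Psi[, k]
  }
  e0 <- sum(as.numeric(x)^2)
  list(coef = coef, approx = as.numeric(x) - r,
       energy_captured = if (e0 > 0) 1 - sum(r^2) / e0 else 1)
}
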