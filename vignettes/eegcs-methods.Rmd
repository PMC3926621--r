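---
title: "Energy-efficient compressed sensing of multichannel EEG: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-efficient compressed sensing of multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A wireless EEG sensor node runs on a battery. Acquisition cannot be avoided,
so the energy budget is dominated by (i) the computations performed before
transmission and (ii) the number of bits put on the radio. Classical
transform codecs (wavelet + thresholding + entropy coding) compress well but
concentrate heavy, adaptive computation at the sensor. Compressed sensing
(CS) moves the asymmetry the other way: the sensor performs only cheap,
non-adaptive linear projections, and the receiving server — which has no
energy constraint — pays the price of solving a convex program per channel.

`eegcs` implements a complete sensor-to-server codec built on that idea,
plus the wavelet comparison codec and the robustness experiments needed to
characterize it, all exercisable on synthetic recordings so that every claim
in the test suite is reproducible without any data download.

# The codec

## Sensor side

One epoch is an `N x C` matrix (default `N = 512` samples at 128 Hz,
`C` channels). The stages are:

1. **Demeaning.** Each channel's mean is removed and carried in the header
   (16-bit fixed point, 1/8 resolution). Removing means narrows the dynamic
   range and makes the difference stage more effective.
2. **Sparse binary projection.** One `M x N` matrix `Phi` with exactly
   `d = 8` ones per column, shared by all channels, maps each channel to
   `M = round(N / CR)` measurements. Because entries are 0/1, the
   projection is `N*d` *additions* per channel — no multiplier is needed —
   and the matrix is regenerated from `(M, N, d, seed)` on both ends rather
   than transmitted. `d = 8` is the saturation point of the reconstruction
   error in the column weight (the `sweep_d()` experiment); larger `d`
   buys nothing and costs additions.
3. **Interchannel difference coding.** Neighbouring electrodes record
   highly correlated signals, and because all channels share `Phi`, their
   measurement vectors inherit that correlation. The server runs a greedy
   selection on the Pearson correlation matrix of the measurement columns:
   repeatedly take the largest remaining `|R[i,j]|` (ties broken by lowest
   index pair), keep the pair only if its signed incidence row
   `e_i - sign(R_ij) e_j` is linearly independent of those already chosen
   (incremental orthogonalization, tolerance 1e-10), stop pairing when `C`
   entries exist or the best remaining correlation falls below `T = 0.6`,
   then fill the remaining slots with minimum-variance independent
   singleton channels. The resulting `C x C` system is invertible by
   construction. The sensor only computes `y_i - sign * y_j` (`M`
   subtractions per pair). Schedules are computed on one epoch and applied
   to the next ("predictive" operation) since the pair structure of
   stationary recordings changes slowly; the refresh interval is a
   configuration knob (`codec_config(pairs = )`), default every epoch.
4. **Quantization.** The interleaved vector (sample-major, so every packet
   carries all channels) is uniformly quantized to 15 bits over
   ±2^14 — three bits of headroom over the 12-bit raw range because a
   measurement is a sum of ~`Nd/M` samples. With these defaults the step
   is exactly 1 raw amplitude unit. The quantizer is mid-rise, so an
   exactly-zero residue reproduces as ±step/2; clipped samples are counted
   and reported.
5. **Entropy coding.** Difference measurements have a narrow, roughly
   Gaussian histogram, so canonical Huffman coding (deterministic
   tie-breaks, codebook trained offline on separate data) is used. An
   escape symbol covers codes absent from training: escape code followed by
   the raw 15-bit value.
6. **Packetization.** 127-byte packets with 13 bytes of MAC overhead leave
   114-byte payloads. Header bits (dimensions, seed, means, pair list,
   codebook id, payload length) are charged against the measured
   compression ratio; MAC overhead is not.

## Server side

Decode, dequantize, invert the difference schedule (one `C x C` solve per
measurement row), then per channel solve basis pursuit denoise

    min ||c||_1  subject to  ||y - Phi Psi c||_2 <= sigma

against a redundant Gabor dictionary `Psi`, and finally `f = Psi c` plus the
stored mean.

### The Gabor dictionary

Atoms are unit-norm sinusoidally modulated Gaussians
`g(n) = K exp(-(n-n0)^2/(2 s^2)) sin(2 pi f0 (n-n0))`. Spreads are dyadic
(`s = 2, 4, ..., N`); per spread the time step is `(2 alpha / pi) s` and the
frequency step `8 pi alpha / (s N)`, with
`alpha = 0.5 ln(0.5 (B + 1/B))` and `B = 2`. The printed source for these
increments is ambiguous, so both constants are exposed
(`gabor_dictionary(c_t =, c_f =)`) and correctness is pinned instead to a
behavioural property: the top `N/8` greedy atoms must capture at least 90%
of a synthetic epoch's energy. Grids are floored at one sample / one DFT
bin, boundary atoms are truncated and renormalized, a DC atom is appended
for the demeaning residue, and the atom count is capped at `16 N` by
scaling both increments up proportionally.

Two non-obvious choices:

* **Near-duplicate pruning** (`dedup_coherence = 0.99`). At large spreads
  the Gaussian window is flat over the epoch and atoms collapse into
  near-identical sinusoids across shifts and scales. Those
  near-dependencies make sparse representations non-identifiable (the l1
  minimizer splits mass across duplicates) and slow the solver, while
  adding nothing to the span. Columns whose absolute inner product with an
  already-kept column exceeds 0.99 are dropped.
* **Identifiability and planted tests.** Even after pruning, a redundant
  frame contains supports whose atoms admit an alternative representation
  of smaller l1 norm. For such supports exact *coefficient* recovery is
  mathematically impossible for any basis-pursuit solver, although the
  *signal* is still recovered (observed signal-space error ~1e-4 in those
  cases). The planted-recovery tests therefore draw supports with mutual
  coherence at most 0.5, the regime that exact-recovery theory addresses.

### The solver

`bpdn_solve()` is a spectral projected-gradient method: LASSO subproblems
(`min ||y - Ac||_2` s.t. `||c||_1 <= tau`) are solved by nonmonotone
projected gradient with Barzilai-Borwein steps (memory 10, sufficient
decrease 1e-4), and `tau` follows Newton's method on the Pareto curve using
the exact derivative `-||A' r||_inf / ||r||`. The duality gap
`tau ||A'r||_inf - c'A'r` controls subproblem termination. For `sigma = 0`
(equality basis pursuit) an active-set least-squares polish is applied: the
SPG iterate identifies the support long before the coefficients settle, and
one QR solve on that support lands on the exact solution. The polish is
accepted only when feasible at `bp_tol` and l1-non-increasing; otherwise the
solve is escalated once with tighter tolerances.

### The residual bound sigma

Quantization contributes a uniform error of variance `step^2/12` per
measurement, aggregated norm `step sqrt(M/12)` (`default_sigma()`). Real
signals also contain a component no sparse Gabor combination represents
(background activity); forcing the residual below that level makes the
solver spend an order of magnitude more iterations encoding background
noise into atoms, with slightly *worse* reconstruction. The automatic rule
is therefore `sigma_j = max(step sqrt(M/12), 0.05 ||y_j||)` per channel;
`recon_config(sigma_rel = 0)` recovers the pure quantization rule, and the
test suite verifies that the quantization rule is never worse than
`sigma = 0` on exactly sparse quantized inputs.

## Packet loss

Packets are plain 114-byte chunks of the Huffman stream, so a lost packet
desynchronizes a variable-length decoder. The loss simulation assumes what
the transmission design assumes — the receiver knows which packets were
dropped and how many measurements each carried — and resynchronizes each
contiguous received run at the first symbol starting inside it, using the
encoder's symbol positions (simulation metadata, not transmitted bits).
Any measurement row with a missing symbol in any channel is discarded for
all channels, and the corresponding rows of `Phi` are deleted before
reconstruction; the row-deleted system is verified in the tests against an
explicitly constructed oracle. Because CS measurements are interchangeable,
quality degrades in proportion to the *number* of lost packets, not their
identity — the graceful-degradation property the packet-loss experiment
quantifies as a flatter NMSE-versus-loss slope than the baseline's.

## Wavelet baseline

The comparison codec transforms each raw channel with a CDF 9/7 lifting
DWT (level 7; perfect reconstruction to 1e-9), keeps the `k`
largest-magnitude coefficients (ties by index), and codes positions (gap
sequence) and 12-bit quantized values with an adaptive order-0 arithmetic
coder. `k` is chosen per channel by searching the *actual* coded size
against the bit budget `N * 12 / CR`. Its packet-loss model zeroes the
coefficients mapped (proportionally by bit position) into lost packets —
deliberately charitable, since a real adaptive arithmetic decoder would
lose everything after the first gap; the CS-versus-baseline slope
comparison is therefore conservative.

# The synthetic generator

`generate_recording()` emulates the three statistical properties the codec
relies on, and nothing else:

* **Gabor-domain compressibility.** Each of `n_sources` latent sources is a
  fresh sparse combination of `atoms_per_source = 12` dictionary atoms per
  epoch, normalized to unit RMS.
* **Interchannel correlation.** Channels mix the sources through a smooth
  spatial-decay matrix `A[c,s] = exp(-(pos_c - pos_s)^2 / (2 lambda^2))`
  with jittered channel positions and random source positions (montages
  are not uniform, and the resulting heterogeneous correlation pattern is
  what keeps the greedy pair schedule stable across epochs, as in real
  recordings). `lambda` is solved numerically so the expected mean pairwise
  |r| — after correcting for the shrinkage caused by per-channel noise —
  hits `mixing_coherence` (default 0.8; realized within ±0.1).
* **1/f background and 12-bit amplitudes.** Per-channel pink noise is added
  at `pink_noise_snr = 20` dB and the recording is scaled and rounded into
  the 12-bit integer range last, so quantization assumptions match.

What it does *not* emulate: physiological morphology (spindles, seizure
patterns), nonstationarity, artifacts, line noise, or volume-conduction
head models. Passing tests demonstrate the pipeline's correctness and its
qualitative robustness ordering, not clinical reconstruction quality on
real EEG; absolute NMSE values on real recordings depend on how well real
signals fit the Gabor model.

`add_gaussian_noise()` scales white noise per channel so the realized SNR
is exact; at 128 Hz sampled white noise occupies 0-64 Hz.

# Numerical choices and degenerate inputs

* Trailing partial windows are dropped at epoching (not padded).
* Dead (identically zero) channels are removed at ingestion with a warning.
* Zero-variance measurement columns get correlation 0 with a warning; the
  singleton fallback keeps the schedule invertible regardless.
* Ties in pair selection break lexicographically; ties in coefficient
  magnitude (baseline thresholding) break by index; Huffman ties break by
  symbol value — all so that independent runs agree bit-for-bit.
* A pair schedule may reuse a channel in several pairs; only linear
  independence is enforced ("removing a pair from the pool" removes the
  entry, not the channels).
* The empty bitstream packetizes to zero packets; a one-symbol Huffman
  alphabet gets a 1-bit code by convention.

# Problem sizes used by the test suite

Solver-bound checks run on synthetic recordings at `N = 512` with 1-4
channels: the pipeline fidelity check uses 30 epochs at CR 2:1 (3 channels)
and a 6-epoch paired sweep across CR {8, 6, 5, 4, 3.5, 3, 2.5, 2}; the
d-saturation and matrix-equivalence experiments use 30 single-channel
epochs per cell; the packet-loss comparison uses 30 two-channel epochs over
losses {0, 3, 6, 9, 12}%. Bit-exactness checks (Huffman, packets,
quantizer codes, difference inversion) run at 500-1000 random instances.
`scripts/acceptance.R` recomputes the same quantities at slightly smaller
epoch counts and prints them as JSON.

# Known limitations

* Channels are reconstructed independently; joint (MMV) reconstruction
  that shares support across channels is out of scope.
* The on-disk format stores the codebook alongside the header for
  self-containment; a deployed system would reference a shared offline
  codebook by id alone.
* The energy accounting is an operation-count proxy plus a cited
  per-packet transmission constant (524.72 uJ); it is not a cycle-accurate
  hardware simulation.
* The pair-list uplink (server to sensor) is counted, not simulated.
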