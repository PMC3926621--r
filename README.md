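# eegcs

Energy-efficient compressed-sensing compression of multichannel EEG for
wireless body sensor networks, in R.

A battery-powered EEG sensor node should spend as little energy as possible
on computation and radio transmission. `eegcs` implements a codec built for
that constraint: the sensor compresses each 512-sample epoch of `C` channels
using only additions, subtractions and table lookups, and the server — which
has no energy budget — does the heavy lifting of reconstruction by convex
optimization.

**Sensor side** (per epoch `F`, `N x C`):

1. remove per-channel means;
2. project every channel with one shared sparse binary matrix `Phi`
   (`M x N`, exactly `d = 8` ones per column): `Y = Phi F_tilde`, costing
   `N d` additions per channel and no multiplications;
3. subtract sign-matched measurement vectors of highly correlated channel
   pairs (schedule chosen server-side by a greedy pass over the Pearson
   correlation matrix with threshold `T = 0.6`, kept invertible by a linear
   independence check): the differences have a much narrower distribution;
4. interleave, quantize to 15 bits, Huffman-code against an offline
   codebook, and pack into 127-byte packets (114-byte payloads).

**Server side:** decode, invert the difference schedule, and recover each
channel by basis pursuit denoising

```
min ||c||_1   subject to   || y - Phi Psi c ||_2 <= sigma
```

against a redundant Gabor frame `Psi` of sinusoidally-modulated Gaussian
atoms (dyadic spreads; time step proportional to the spread, frequency step
inversely proportional), then `f_hat = Psi c_hat + mean`. Quality is scored
as `NMSE = ||x - x_hat||^2 / ||x - mean(x)||^2` and rate as
`CR = original bits / compressed bits`.

The package also provides the standard comparison codec (CDF 9/7 wavelet
transform, hard top-k thresholding, adaptive arithmetic coding), a synthetic
multichannel EEG generator (correlated channels, Gabor-compressible sources,
1/f background, 12-bit amplitudes), and experiment drivers for the
measurement-matrix design studies and the Gaussian-noise and packet-loss
robustness comparisons.

## Worked example

```r
library(eegcs)

# a synthetic 4-channel recording: correlated channels, compressible sources
scfg <- synth_config(C = 4, N = 512, n_epochs = 2, seed = 42)
rec  <- generate_recording(scfg)
e    <- epoch_stream(rec, 512)[[1]]

cz <- compress_epoch(e, codec_config(target_cr = 2, d = 8, seed = 7))
cz
#> <compressed_epoch> N = 512, C = 4, M = 256, d = 8, 11 packets, measured CR 2.42:1

dict <- gabor_dictionary(512)
rc   <- reconstruct_epoch(cz, dict)
round(sapply(1:4, function(j) nmse(e[, j], rc$F_rec[, j])), 4)
#> [1] 0.0411 0.0648 0.0415 0.0197
```

The measured 2.42:1 exceeds the 2:1 target because entropy coding of the
narrow difference distribution saves bits beyond the measurement
subsampling; the per-channel NMSE around 0.02-0.06 means each reconstructed
channel retains ~94-98% of the (demeaned) signal energy. Dropping packets
degrades this gracefully: with the same epoch and 10% of packets lost, the
affected measurement rows are deleted before solving and NMSE rises only
moderately, whereas the wavelet baseline loses its largest coefficients
outright (see `run_packet_loss_experiment()`).

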