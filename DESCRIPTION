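Package: eegcs
Title: Energy-Efficient Compressed Sensing Codec for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Sensor-side compression and server-side reconstruction of
    multichannel electroencephalogram (EEG) recordings for wireless body
    sensor networks. Each channel is projected with a shared sparse binary
    sensing matrix (addition-only), interchannel redundancy is removed by
    sign-matched difference coding of correlated channel pairs, and the
    residuals are uniformly quantized, Huffman coded and packetized. The
    server inverts the difference schedule and recovers each channel by
    basis pursuit denoising against a redundant Gabor dictionary. Includes
    a CDF 9/7 wavelet baseline codec with arithmetic coding, a synthetic
    multichannel EEG generator, and experiment drivers for measurement
    matrix comparison, Gaussian noise and packet-loss robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
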