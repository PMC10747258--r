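Package: fetalhr
Title: Robust Fetal Heart Rate Estimation from Doppler Ultrasound with
    Unsupervised Signal Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates beat-to-beat fetal heart rate from single-channel
    Doppler ultrasound recordings. Raw audio is band-passed to the fetal
    cardiac band (25-500 Hz), converted to a short-time Fourier transform
    power envelope (the integrated spectrum), and beat intervals are
    extracted by a double autocorrelation procedure with adaptive window
    sizing. Segment quality is scored without labels by a one-dimensional
    convolutional variational autoencoder whose latent means feed a
    self-organizing map; the quantization error is mapped to a signal
    quality index in [0, 1]. Estimates are refined by a cascade of a
    fixed-noise and a quality-adaptive scalar Kalman filter, and estimates
    from long low-quality runs are discarded. A synthetic Doppler
    ultrasound simulator with known beat times supports end-to-end
    evaluation (RMSE, absolute FHR error, coverage) when no annotated
    recordings are available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
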