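sine_recording <- function(freq, fs = 1000, dur = 4) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  dus_recording(sin(2 * pi * freq * tt), fs = fs)
}

fft_amplitude <- function(x, freq, fs) {
  n <- length(x)
  2 * Mod(fft(x))[round(freq * n / fs) + 1L] / n
}

test_that("band-pass keeps in-band tones and rejects out-of-band ones", {
  zero <- dus_recording(numeric(1000), fs = 1000)
  expect_equal(bandpass(zero)$amplitude, numeric(1000))

  rec <- sine_recording(100)
  out <- bandpass(rec, 25, 500)
  expect_equal(nrow(out), nrow(rec))
  # interior amplitude via FFT ratio oracle (trim filter edge effects)
  mid <- 501:3500
  amp <- fft_amplitude(out$amplitude[mid], 100, 1000)
  expect_equal(amp, 1, tolerance = 0.01)

  slow <- sine_recording(5)
  att <- fft_amplitude(bandpass(slow, 25, 500)$amplitude[501:3500], 5, 1000)
  expect_lt(20 * log10(att / 1), -20)

  expect_error(bandpass(rec, 25, 600), "Nyquist")
  expect_error(bandpass(rec, 0, 500), "0 < lo")
})

test_that("stft frames tile the recording and locate tones", {
  zero <- dus_recording(numeric(2000), fs = 1000)
  sp0 <- stft(zero)
  expect_true(all(sp0$power == 0))
  expect_equal(ncol(sp0$power), 2000)  # one frame per ms

  rec <- sine_recording(200, dur = 2)
  sp <- stft(rec)
  interior <- seq(200, 1800, by = 100)
  for (j in interior) {
    # brute-force DFT oracle on the same Hann-windowed frame
    wl <- round(sp$window_len * 1000)
    half <- wl %/% 2
    c0 <- round(sp$frame_times[j] * 1000) + 1
    seg <- rec$amplitude[max(1, c0 - half):min(nrow(rec), c0 - half + wl - 1)]
    seg <- c(seg, numeric(wl - length(seg)))
    taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(wl) / (wl + 1))
    dft <- vapply(seq_along(sp$freqs), function(b) {
      k <- b - 1
      Mod(sum(seg * taper * exp(-2i * pi * k * (seq_len(wl) - 1) / wl)))^2
    }, numeric(1))
    expect_equal(which.max(sp$power[, j]), which.max(dft))
    expect_lt(abs(sp$freqs[which.max(sp$power[, j])] - 200),
              1000 / wl + 1e-9)  # within one bin
  }

  expect_error(stft(dus_recording(numeric(10), fs = 1000)), "shorter")
  expect_error(stft(rec, window_len = 0.004, step = 0.008), "window_len")
})

test_that("band integration is nonnegative, per-frame, and quadratic in amplitude", {
  rec <- sine_recording(200, dur = 2)
  sp <- stft(rec)
  s1 <- integrate_spectrum(sp, 25, 500)
  expect_equal(nrow(s1), ncol(sp$power))
  expect_true(all(s1$power >= 0))

  interior <- s1$power[200:1800]
  expect_lt((max(interior) - min(interior)) / mean(interior), 0.05)

  rec2 <- dus_recording(2 * rec$amplitude, fs = 1000)
  s2 <- integrate_spectrum(stft(rec2), 25, 500)
  expect_equal(s2$power, 4 * s1$power, tolerance = 1e-12)

  expect_error(integrate_spectrum(sp, 501, 502), "bins")

  szero <- integrate_spectrum(stft(dus_recording(numeric(2000), 1000)))
  expect_true(all(szero$power == 0))
})

test_that("spike removal replaces isolated spikes and nothing else", {
  tt <- seq(0, 10, by = 0.01)
  smooth <- integrated_spectrum(2 + sin(2 * pi * 0.2 * tt), step = 0.01)
  expect_equal(remove_spikes(smooth)$power, smooth$power)

  spiked <- smooth
  spiked$power[500] <- 100 * spiked$power[500]
  fixed <- remove_spikes(spiked)
  expect_equal(fixed$power[500], smooth$power[500], tolerance = 0.01)
  expect_equal(fixed$power[-500], smooth$power[-500])

  const <- integrated_spectrum(rep(3, 200), step = 0.01)
  const$power[100] <- 50
  expect_equal(remove_spikes(const)$power, rep(3, 200))

  expect_error(remove_spikes(smooth, win = 4), "odd")
})

test_that("pre-processing is deterministic and aligns peaks with beats", {
  fx <- clean_fixture()
  env2 <- preprocess(fx$rec)
  expect_identical(fx$env$power, env2$power)

  # local maxima of the envelope should sit near annotated beat times
  p <- fx$env$power
  win <- 25  # +/- 25 ms dominance window
  peaks <- which(vapply(seq(win + 1, length(p) - win), function(i) {
    p[i] == max(p[(i - win):(i + win)])
  }, logical(1))) + win
  peak_t <- fx$env$time[peaks]
  beats <- attr(fx$rec, "schedule")$beat_time
  matched <- vapply(beats[beats > 1 & beats < 59], function(b) {
    min(abs(peak_t - b)) <= 0.020
  }, logical(1))
  expect_gt(mean(matched), 0.9)
})

test_that("integrated spectrum csv round-trips", {
  s <- integrated_spectrum(runif(100), step = 0.001)
  path <- withr::local_tempfile(fileext = ".csv")
  write_integrated_csv(s, path)
  back <- read_integrated_csv(path)
  expect_equal(back$power, s$power, tolerance = 1e-12)
  expect_equal(attr(back, "step"), 0.001)
})
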