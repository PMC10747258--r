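test_that("constant beat schedule places the expected beats", {
  sched <- make_beat_schedule(60, "constant", base_frri = 0.4)
  expect_equal(nrow(sched), 150)
  expect_equal(sched$beat_time[1], 0)
  expect_true(all(abs(diff(sched$beat_time) - 0.4) < 1e-9))
})

test_that("sinusoidal modulation keeps gaps inside the stated band", {
  sched <- make_beat_schedule(60, "sinusoidal", base_frri = 0.4,
                              modulation = list(amp = 0.05, period = 10))
  gaps <- diff(sched$beat_time)
  expect_true(all(gaps >= 0.35 - 1e-9 & gaps <= 0.45 + 1e-9))
})

test_that("piecewise schedules follow their breakpoints and bad modulation errors", {
  sched <- make_beat_schedule(
    20, "piecewise", base_frri = 0.4,
    modulation = list(times = c(0, 10), values = c(0.4, 0.5))
  )
  gaps <- diff(sched$beat_time)
  mids <- sched$beat_time[-1] - gaps / 2
  expect_true(all(abs(gaps[mids < 9.9] - 0.4) < 1e-9))
  expect_true(all(abs(gaps[mids > 10.1] - 0.5) < 1e-9))
  expect_error(
    make_beat_schedule(60, "sinusoidal", base_frri = 0.3,
                       modulation = list(amp = 0.2, period = 10)),
    "outside"
  )
  expect_error(make_beat_schedule(60, "constant", base_frri = 0.1), "0.25")
})

test_that("schedules and recordings are reproducible under a fixed seed", {
  s1 <- make_beat_schedule(60, "constant", base_frri = 0.4, seed = 3L)
  s2 <- make_beat_schedule(60, "constant", base_frri = 0.4, seed = 3L)
  expect_identical(s1$beat_time, s2$beat_time)
  r1 <- synthesize_recording(s1, seed = 12L)
  r2 <- synthesize_recording(s2, seed = 12L)
  expect_identical(r1$amplitude, r2$amplitude)
})

test_that("an empty schedule yields a pure noise floor", {
  rec <- synthesize_recording(empty_schedule(2), fs = 1000, seed = 1L)
  expect_equal(nrow(rec), 2000)
  # white noise: no band-limited burst structure, roughly zero-mean
  expect_lt(abs(mean(rec$amplitude)), 0.1)
  expect_error(
    synthesize_recording(empty_schedule(2), fs = 1000,
                         burst = list(carrier_hi = 600), seed = 1L),
    "carriers"
  )
  expect_error(synthesize_recording(empty_schedule(2), fs = 500), "1000")
})

test_that("band energy of a synthesized recording peaks at the beat period", {
  sched <- make_beat_schedule(20, "constant", base_frri = 0.4)
  rec <- synthesize_recording(sched, fs = 1000, snr_db = 20, seed = 2L)
  env <- preprocess(rec)
  y <- env$power[1:10000]
  a <- acf_bruteforce(y - mean(y), max_lag = 1300)
  search <- 251:1201  # lags 0.25-1.2 s at 1 ms
  peak_lag <- (search[which.max(a[search])] - 1) / 1000
  expect_lt(abs(peak_lag - 0.4), 0.005)
})

test_that("corruption flags episodes, raises their power, and keeps the truth", {
  sched <- make_beat_schedule(60, "constant", base_frri = 0.4)
  rec <- synthesize_recording(sched, seed = 4L)

  expect_identical(corrupt_recording(rec, fraction_corrupted = 0), rec)

  cor1 <- corrupt_recording(rec, fraction_corrupted = 0.1, episode_len = 1.2,
                            noise_gain = 5, seed = 9L)
  cor2 <- corrupt_recording(rec, fraction_corrupted = 0.1, episode_len = 1.2,
                            noise_gain = 5, seed = 9L)
  expect_identical(cor1$amplitude, cor2$amplitude)

  # ~10% of 60 s in 1.2 s episodes -> ~6 s masked
  masked_s <- sum(cor1$corrupted) / sampling_rate(cor1)
  expect_equal(masked_s, 6, tolerance = 0.3)

  expect_identical(attr(cor1, "schedule")$beat_time, sched$beat_time)

  # within-episode power exceeds clean power at noise_gain > 1
  p_cor <- mean(cor1$amplitude[cor1$corrupted]^2)
  p_cln <- mean(cor1$amplitude[!cor1$corrupted]^2)
  expect_gt(p_cor, p_cln)
})

test_that("wav and csv round-trips preserve the waveform", {
  sched <- make_beat_schedule(2, "constant", base_frri = 0.4)
  rec <- synthesize_recording(sched, seed = 5L)

  wav <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, wav)
  back <- read_wav(wav)
  expect_equal(sampling_rate(back), 1000)
  # 16-bit quantization after peak normalization
  scale <- max(abs(rec$amplitude))
  expect_equal(back$amplitude * scale, rec$amplitude, tolerance = 1e-3)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, csv)
  back2 <- read_recording_csv(csv)
  expect_equal(back2$amplitude, rec$amplitude, tolerance = 1e-6)
  expect_equal(sampling_rate(back2), 1000)

  ann <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(sched, ann)
  expect_equal(read_annotations_csv(ann)$beat_time, sched$beat_time)
})
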