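test_that("quantization error is the exhaustive minimum distance", {
  set.seed(51)
  x <- matrix(rnorm(300 * 8), 300)
  som <- train_som(x, grid = c(30L, 30L), iterations = 500L, seed = 3L)
  for (i in 1:10) {
    v <- rnorm(8)
    brute <- min(sqrt(rowSums(sweep(som$weights, 2, v)^2)))
    expect_equal(quantization_error(som, v), brute, tolerance = 1e-12)
  }
  # a vector equal to some neuron's weight has zero error
  expect_equal(quantization_error(som, som$weights[17, ]), 0)
  expect_error(quantization_error(som, rnorm(5)), "dimension")
})

test_that("a one-neuron map gives plain Euclidean distance", {
  som <- structure(
    list(weights = matrix(c(1, 2, 3), 1), grid = c(1L, 1L),
         gx = 1L, gy = 1L, iterations = 0L, lr = 0.5, sigma = 0.5, d = 3L),
    class = "dus_som"
  )
  expect_equal(quantization_error(som, c(1, 2, 7)), 4)
})

test_that("training collapses onto a repeated vector and separates clusters", {
  v <- c(1, -2, 3, 0.5)
  x <- matrix(rep(v, each = 50), 50)
  som <- train_som(x, grid = c(5L, 5L), iterations = 2000L, seed = 1L)
  expect_lt(quantization_error(som, v), 1e-6)

  set.seed(52)
  c1 <- matrix(rnorm(100 * 4, mean = 0, sd = 0.3), 100)
  c2 <- matrix(rnorm(100 * 4, mean = 5, sd = 0.3), 100)
  som2 <- train_som(rbind(c1, c2), grid = c(10L, 10L), iterations = 3000L,
                    seed = 2L)
  qe <- quantization_error(som2, rbind(c1, c2))
  between <- sqrt(sum((colMeans(c1) - colMeans(c2))^2))
  expect_lt(mean(qe), between)

  # determinism
  som3 <- train_som(rbind(c1, c2), grid = c(10L, 10L), iterations = 3000L,
                    seed = 2L)
  expect_identical(som2$weights, som3$weights)
})

test_that("combined SQI follows the thresholded linear ramp", {
  out <- combined_sqi(c(2, 4, 6))
  expect_equal(out$qe_norm, c(0, 0.5, 1))

  # explicit threshold cases via frozen stats: th = 0.6
  st <- list(qe_min = 0, qe_max = 1, th = 0.6)
  sc <- combined_sqi(c(0.2, 0.6, 0.8, 1.0), stats = st)
  expect_equal(sc$sqi, c(1, 1, 0.5, 0))

  # all equal -> degenerate normalization -> full quality
  expect_equal(combined_sqi(rep(3, 5))$sqi, rep(1, 5))
})

test_that("SQI is in [0,1], non-increasing in QE, and mostly 1 at the 9th decile", {
  set.seed(53)
  qes <- sort(rexp(200))
  out <- combined_sqi(qes)
  expect_true(all(out$sqi >= 0 & out$sqi <= 1))
  expect_true(all(diff(out$sqi) <= 1e-12))  # sorted qes -> non-increasing sqi
  expect_gte(mean(out$sqi == 1), 0.9)
})

test_that("segments align to window starts and resample to 1024 samples", {
  s <- integrated_spectrum(rep(2.5, 5000), step = 0.001)
  segs <- segment_for_sqa(s, starts = c(0, 0.5, 1.0), win = 1.2)
  expect_equal(nrow(segs), 3)
  expect_true(all(vapply(segs$x, length, integer(1)) == 1024L))
  expect_true(all(vapply(segs$x, function(v) all(v == 2.5), logical(1))))

  ramp <- integrated_spectrum(seq_len(2000), step = 0.001)
  sg <- segment_for_sqa(ramp, starts = 0.1, win = 1.2)
  # endpoint-preserving linear resampling of samples 101..1300
  expect_equal(sg$x[[1]][1], 101)
  expect_equal(sg$x[[1]][1024], 1300)

  expect_warning(
    tail_seg <- segment_for_sqa(ramp, starts = c(0, 1.5), win = 1.2),
    "skipped"
  )
  expect_equal(nrow(tail_seg), 1)
})

test_that("window starts inherit the nearest preceding segment score", {
  est <- tibble::tibble(window_start = c(0, 0.5, 1.0, 1.5),
                        frri_est = rep(0.4, 4))
  scores <- tibble::tibble(start = c(0, 0.5, 1.0), sqi = c(1, 0.7, 0.2))
  out <- align_sqi(est, scores)
  expect_equal(out$sqi, c(1, 0.7, 0.2, 0.2))
})

test_that("the fitted quality model separates corrupted from clean segments", {
  # one 60 s recording with 15% artifact episodes; light training settings
  sched <- make_beat_schedule(60, "constant", base_frri = 0.4)
  rec <- synthesize_recording(sched, seed = 61L)
  rec <- corrupt_recording(rec, fraction_corrupted = 0.15, noise_gain = 5,
                           seed = 62L)
  env <- preprocess(rec)
  est <- track_frri(env)
  segs <- segment_for_sqa(env, est$window_start)
  lab <- segment_labels(rec, segs$start)

  model <- sqa_fit(segs,
                   vae_cfg = vae_config(epochs = 6L, seed = 1L),
                   som_iterations = 1000L)
  sc <- model$train_scores
  expect_true(all(sc$sqi >= 0 & sc$sqi <= 1))
  expect_lt(mean(sc$sqi[lab]), mean(sc$sqi[!lab]))

  # scoring the training corpus against frozen stats reproduces the scores
  rescored <- sqa_score(model, segs)
  expect_equal(rescored$sqi, sc$sqi, tolerance = 1e-12)

  g <- glance(model)
  expect_equal(g$n_train, nrow(segs))
  expect_true(g$th >= 0 && g$th <= 1)
})
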