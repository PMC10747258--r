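# Independent oracles and shared fixtures for the test suite.

# Brute-force normalized autocorrelation: literal double loop over
#   sum_{i=1}^{N-k} (y_i - ybar)(y_{i+k} - ybar) / sum_i (y_i - ybar)^2
acf_bruteforce <- function(y, max_lag = length(y) - 1L) {
  n <- length(y)
  yb <- mean(y)
  denom <- sum((y - yb)^2)
  vapply(0:max_lag, function(k) {
    num <- 0
    for (i in seq_len(n - k)) num <- num + (y[i] - yb) * (y[i + k] - yb)
    num / denom
  }, numeric(1))
}

# Independently coded scalar Kalman recursion (predict/gain/update)
kalman_oracle <- function(z, R, Q, x0, P0) {
  x <- x0
  p <- P0
  out <- numeric(length(z))
  if (length(R) == 1L) R <- rep(R, length(z))
  for (m in seq_along(z)) {
    pp <- p + Q
    k <- pp / (pp + R[m])
    x <- x + k * (z[m] - x)
    p <- (1 - k) * pp
    out[m] <- x
  }
  out
}

# Rank (Mann-Whitney) AUC of a score against binary labels
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Label quality segments by overlap with the corruption mask. Artifact
# episodes run at ~25x the clean band power, so even a 5% overlap dominates
# a segment's energy; any meaningfully overlapping segment is "corrupted".
segment_labels <- function(rec, starts, win = 1.2, min_overlap = 0.05) {
  fs <- sampling_rate(rec)
  vapply(starts, function(t0) {
    idx <- (round(t0 * fs) + 1):min(round((t0 + win) * fs), nrow(rec))
    mean(rec$corrupted[idx]) > min_overlap
  }, logical(1))
}

# An empty beat schedule (pure noise floor) of the given duration
empty_schedule <- function(duration) {
  out <- tibble::tibble(beat_time = numeric())
  class(out) <- c("beat_schedule", class(out))
  attr(out, "pattern") <- "constant"
  attr(out, "duration") <- duration
  out
}

# Shared clean 60 s constant-rate fixture (computed once per test run)
.fixture_env <- new.env(parent = emptyenv())

clean_fixture <- function() {
  if (is.null(.fixture_env$clean)) {
    sched <- make_beat_schedule(60, "constant", base_frri = 0.4)
    rec <- synthesize_recording(sched, fs = 1000, seed = 7L)
    env <- preprocess(rec)
    est <- track_frri(env)
    .fixture_env$clean <- list(sched = sched, rec = rec, env = env, est = est)
  }
  .fixture_env$clean
}

# Small trained VAE on a cheap synthetic corpus (shared across tests)
tiny_vae_fixture <- function() {
  if (is.null(.fixture_env$tiny_vae)) {
    set.seed(99)
    n <- 48
    base <- sin(seq(0, 6 * pi, length.out = 64))^2
    m <- t(vapply(seq_len(n), function(i) {
      base * runif(1, 0.5, 2) + rnorm(64, sd = 0.05)
    }, numeric(64)))
    cfg <- vae_config(input_len = 64L, channels = c(4L, 8L), latent_dim = 4L,
                      kernel = 8L, stride = 2L, epochs = 8L, batch = 16L,
                      seed = 5L)
    .fixture_env$tiny_vae <- list(m = m, cfg = cfg,
                                  model = train_vae(m, cfg))
  }
  .fixture_env$tiny_vae
}
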