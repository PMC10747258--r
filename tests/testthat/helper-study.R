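# The corrupted-recording study shared by the quality-assessment and
# refinement acceptance checks: one 5-minute constant-rate recording with 10%
# of its duration overwritten by movement-artifact noise (gain 5), the
# quality model trained at 30 epochs / 3000 SOM iterations. Fitted once per
# test run and cached; the scenario harness reuses the default-seed fit.

study_fixture <- function() {
  if (is.null(.fixture_env$study)) {
    sched <- make_beat_schedule(300, "constant", base_frri = 0.4)
    rec <- synthesize_recording(sched, fs = 1000, seed = 11L)
    rec <- corrupt_recording(rec, fraction_corrupted = 0.1,
                             episode_len = 1.2, noise_gain = 5, seed = 111L)
    env <- preprocess(rec)
    est <- track_frri(env)
    segs <- segment_for_sqa(env, est$window_start)
    lab <- segment_labels(rec, segs$start)
    .fixture_env$study <- list(sched = sched, rec = rec, env = env,
                               est = est, segs = segs, lab = lab,
                               fits = list())
  }
  .fixture_env$study
}

study_fit <- function(seed) {
  st <- study_fixture()
  key <- as.character(seed)
  if (is.null(st$fits[[key]])) {
    st$fits[[key]] <- sqa_fit(
      st$segs,
      vae_cfg = vae_config(epochs = 30L, seed = seed),
      som_iterations = 3000L, som_seed = seed
    )
    .fixture_env$study <- st
  }
  st$fits[[key]]
}
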