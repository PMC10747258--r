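# fetalhr

Robust beat-to-beat fetal heart-rate (FHR) estimation from single-channel
Doppler ultrasound (DUS) audio, with unsupervised signal-quality assessment.

A DUS transducer on the maternal abdomen returns an audio-band signal in
which fetal cardiac wall/valve motion appears as short bursts of 25–500 Hz
energy. `fetalhr` turns such a recording into a beat-interval (FRRI) and
heart-rate trace in four stages:

1. **Pre-processing.** Band-pass 25–500 Hz, STFT (64 ms Hann window, 1 ms
   hop), integration of spectral power over 25–500 Hz per frame, robust
   despiking. The result — the *integrated spectrum* — is a 1 kHz envelope
   with one sharp peak per heartbeat.
2. **Double-autocorrelation estimation.** On each sliding window the
   normalized autocorrelation
   `acf_k = Σ_{i≤N−k}(Y_i−Ȳ)(Y_{i+k}−Ȳ) / Σ_i(Y_i−Ȳ)²`
   is computed twice: a 3.75 s window gives an approximate interval
   `FRRI_app` (dominant non-harmonic peak in [0.25, 1.2] s ≙ 240–50 bpm);
   the window is resized to `S_new = 2.5·FRRI_app` and a second ACF,
   restricted to `FRRI_app ± 0.1 s`, yields the refined `FRRI_est`.
   Windows advance by `FRRI_est / 2`.
3. **Signal-quality assessment (SQA).** 1.2 s envelope segments aligned to
   the analysis windows are resampled to 1024 samples and encoded by a 1-D
   convolutional variational autoencoder (5 blocks, kernel 16, stride 2,
   latent dimension 32, ELU + batch norm, loss = mean squared
   reconstruction error + KL divergence to N(0, I)). A 30×30
   self-organizing map over the latent means gives each segment a
   quantization error QE; after min–max normalization, segments below the
   90th-percentile threshold `th` get SQI 1 and quality falls linearly to 0
   at the maximum: `SQI = 1 − (QẼ − th)/(1 − th)`.
4. **SQI-adaptive refinement.** A scalar Kalman filter (R₀ = 1, Q₀ = 0.1)
   smooths the raw intervals; a second filter (R₀ = 1, Q₀ = 1) re-filters
   with measurement noise inflated as `Rm = R₀·e^{1/SQI² − 1}`, and
   estimates from ≥ 4 consecutive low-quality segments (SQI below the 8th
   decile) are discarded. FHR = 60 / FRRI.

Because annotated clinical DUS data are rarely shareable, the package also
ships a synthetic DUS simulator (tone-burst beats with exact ground-truth
beat times, controllable artifact corruption) and an evaluation harness
(FRRI RMSE in ms, absolute FHR error in bpm, coverage in %) comparing four
scenarios: raw estimates, low-SQI removal, conventional Kalman filtering,
and the full pipeline.

## Worked example

```r
library(fetalhr)

# a 60 s recording at 1 kHz, one beat every 0.4 s (150 bpm), with 10% of
# its duration overwritten by movement artifacts
sched <- make_beat_schedule(60, "constant", base_frri = 0.4)
rec   <- synthesize_recording(sched, fs = 1000, seed = 1) |>
  corrupt_recording(fraction_corrupted = 0.1, noise_gain = 5, seed = 2)

env <- preprocess(rec)          # integrated 25-500 Hz spectrum, despiked
est <- track_frri(env)          # double-ACF beat intervals
est
#> # A tibble: 262 × 5
#>   window_start frri_app s_new frri_est ok
#>          <dbl>    <dbl> <dbl>    <dbl> <lgl>
#> 1        0          0.4     1    0.398 TRUE
#> 2        0.199      0.4     1    0.398 TRUE
#> 3        0.398      0.4     1    0.398 TRUE
#> # i 259 more rows

segs  <- segment_for_sqa(env, est$window_start)
model <- sqa_fit(segs, vae_cfg = vae_config(epochs = 30, seed = 1),
                 som_iterations = 3000)
trace <- refine_frri(align_sqi(est, model$train_scores))

pairs <- pair_with_truth(trace, sched)
fhr_metrics(pairs, total_estimates = nrow(trace),
            n_kept = sum(trace$kept))
#> # A tibble: 1 × 4
#>   rmse_ms aae_bpm coverage_pct n_pairs
#>     <dbl>   <dbl>        <dbl>   <int>
#> 1    41.3    6.67         96.6     252
```

`track_frri()` emits one row per analysis window (`window_start` advances
by half the previous interval; `ok` flags windows whose ACF had a usable
peak): on clean stretches it recovers the 0.4 s interval to ~1-2 ms.
`refine_frri()` returns the raw, smoothed and quality-refined interval
series with per-estimate `kept` flags, and `fhr_metrics()` reports interval
RMSE (ms), absolute FHR error (bpm) and coverage (%) against the
simulator's ground truth — here dominated by the 10% of windows overlapping
artifact episodes, most of which are down-weighted or discarded (96.6%
coverage retained). `run_scenarios(rec)` runs the whole four-scenario
comparison in one call. `autoplot()` methods exist for recordings,
integrated spectra, trained autoencoders and refined traces; `tidy()` /
`glance()` for the model objects.

A thin command-line front end over the same functions lives in
`inst/cli/fhr.R` (subcommands `simulate`, `preprocess`, `estimate`, `sqa`,
`refine`, `evaluate`).

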