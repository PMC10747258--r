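---
title: "Robust fetal heart-rate estimation from Doppler ultrasound: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust fetal heart-rate estimation from Doppler ultrasound: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A Doppler ultrasound (DUS) transducer on the maternal abdomen returns an
audio-band signal modulated by fetal cardiac wall and valve motion. The
clinical quantity of interest is the beat-to-beat fetal RR interval (FRRI)
and its reciprocal, the fetal heart rate (FHR = 60 / FRRI in bpm). DUS
signals are noisy — maternal movement, fetal movement and probe slippage all
produce artifact episodes — so a robust estimator must both (i) extract beat
intervals from a quasi-periodic, broadband signal and (ii) recognise when a
stretch of signal is too degraded to trust.

`fetalhr` implements a four-stage pipeline:

1. **Pre-processing** — band-pass 25–500 Hz, short-time Fourier transform
   (64 ms Hann window, 1 ms hop), integration of spectral power over
   25–500 Hz per frame, and robust despiking. The result (the *integrated
   spectrum*) is a 1 kHz envelope in which every heartbeat is a sharp peak.
2. **Double-autocorrelation interval estimation** — on a sliding window the
   normalized autocorrelation (ACF) is computed twice: a fixed 3.75 s window
   yields an approximate interval from the dominant non-harmonic ACF peak in
   [0.25, 1.2] s; the window is then resized to `2.5 ×` that interval and a
   second ACF, restricted to ±0.1 s of the first estimate, refines it. The
   window advances by half the estimated interval.
3. **Unsupervised signal-quality assessment (SQA)** — 1.2 s envelope
   segments aligned with the analysis windows are resampled to 1024 samples
   and encoded by a 1-D convolutional variational autoencoder (VAE); a
   self-organizing map (SOM) over the latent means turns each segment into a
   quantization error (QE), which is min–max normalized and mapped through a
   thresholded linear ramp to a signal-quality index SQI ∈ [0, 1].
4. **SQI-adaptive refinement** — a conventional scalar Kalman filter
   (R₀ = 1, Q₀ = 0.1) smooths the raw intervals; a second filter
   (R₀ = 1, Q₀ = 1) re-filters them with the measurement-noise covariance
   inflated as `Rm = R₀·exp(1/SQI² − 1)`, and estimates from runs of four or
   more consecutive low-quality segments (SQI below the 8th decile) are
   discarded.

Because annotated clinical DUS recordings are rarely shareable, the package
ships a synthetic DUS generator with exact beat-time ground truth, and an
evaluation harness (RMSE of FRRI in ms, average absolute FHR error in bpm,
coverage in %) that compares four processing scenarios: raw estimates,
low-SQI removal, conventional Kalman filtering, and the full pipeline.

## The synthetic generator: what it emulates, and what it does not

Each beat contributes two Gaussian-windowed tone bursts (~50 ms wide,
emulating valve opening and closing) with carriers drawn uniformly in
100–300 Hz; the second burst trails the first by 80 ms at 0.6 relative
amplitude, so each cardiac cycle has one dominant energy event and the ACF
of the envelope has a single peak per period. White noise sets the baseline
at 10 dB SNR. Artifact episodes overwrite 1.2 s slots with broadband noise
at 5× the recording RMS and are flagged in a per-sample mask that the
pipeline never sees — only the evaluation uses it.

This emulates the statistical structure the estimator relies on
(band-limited quasi-periodicity, localized high-amplitude artifacts) but not
the physics of tissue propagation, maternal-heart interference, probe
retuning, or the morphology drift of real recordings. A passing test
therefore shows the algorithms implement their contracts and behave
sensibly under controlled degradation — not clinical performance.

Defaults that define the study conditions: 60 s recordings at 1 kHz for
parameter-recovery checks (constant 0.4 s interval, and sinusoidal
0.35–0.45 s with a 10 s period); one 5-minute recording with 10% of its
duration corrupted at noise gain 5 for the quality-assessment and
refinement study. For that last recording the beat interval is held constant
at 0.4 s: the scenario comparison expects conventional Kalman smoothing to
reduce the absolute FHR error, which presupposes intrinsic rate variation
slow relative to the filter bandwidth — the regime the method targets,
where estimation noise is fast and genuine heart-rate drift is slow.
A fast sinusoidal modulation would superimpose a filter-lag error of several
bpm on every window and the comparison would measure the modulation choice,
not the quality-assessment mechanism. Varying-rate tracking is instead
exercised on clean recordings, where no filter is involved.

## Estimator details and numerical choices

* **ACF** is the mean-subtracted, full-sum-denominator estimator; the
  numerator is evaluated exactly by zero-padded FFT, and a brute-force
  double loop serves as the test oracle. `acf₀ = 1` and `|acf| ≤ 1` always.
* **Peaks** are strict local maxima; ties break toward smaller lags
  (favouring the fundamental). A peak whose half-lag neighbourhood
  (±0.05 s) holds a local maximum with at least 0.75 of its ACF value is
  treated as a harmonic and replaced by that sub-multiple, recursively.
  The 0.25–1.2 s search range corresponds to 240–50 bpm, bracketing the
  physiological fetal range; both bounds are configurable.
* **Window geometry**: the resized second window is anchored at the same
  start as the first, `S_new = 2.5 × FRRI_app` (two beats plus half a beat
  of slack), which never exceeds the 3.75 s first window for intervals up
  to 1.2 s. Lag resolution is the 1 ms envelope step; no sub-sample
  interpolation is attempted since the target errors are ≥ 1 ms.
* **Failed windows**: if a pass finds no peak the window is flagged
  (`ok = FALSE`), the estimate carries the approximate value when one
  exists, and the tracker still advances (by `frri_app/2`, else `S/2`) so
  timestamps stay monotone. Windows where even the first pass fails emit no
  measurement at all and are excluded from evaluation and coverage counts
  — they are not estimates.
* **Despiking** replaces samples above the rolling median + 5 rolling MADs
  (51-frame window) by the rolling median; the rolling MAD is itself a
  rolling median of absolute deviations, so the detector is not blinded by
  the spikes it removes.
* Band-passing uses a 4th-order Butterworth applied forward–backward
  (zero phase, so beat timing is unshifted). With the default 500 Hz upper
  edge at a 1 kHz rate the upper cutoff sits exactly at Nyquist and the
  filter degenerates to a high-pass at 25 Hz — there is no content above
  Nyquist to remove.

## The quality model

The VAE follows a fixed skeleton: five convolution blocks
(convolution → batch normalization → ELU) with kernel 16 and stride 2
compress the 1024-sample segment to a 32-position × 40-channel map; dense
heads emit a 32-dimensional latent mean and log-variance; the decoder
mirrors the encoder with transposed convolutions and a linear final layer.
The loss is the per-sample mean squared reconstruction error plus the
Kullback–Leibler divergence of the latent Gaussian from the standard
normal, optimized by Adam (learning rate 1e-3) on shuffled mini-batches of
64. Free choices made here: the intermediate channel counts (8-12-16-24-40,
a lean progression into the fixed 40-channel bottleneck, sized so training
is practical on a single CPU), per-segment min–max normalization of inputs
to [0, 1] (the quality signal is waveform shape, not absolute power), and
log-variance clamping to [−10, 10] for numerical safety. The network is
implemented directly in the package (im2col convolutions on BLAS with
C++ inner loops and hand-derived backpropagation, verified against finite
differences in the test suite), so training is fully reproducible from a
seed.

With this loss the divergence term drives much of the latent toward the
prior as training proceeds (a familiar property of unweighted VAE
objectives); the latent means nevertheless retain enough structure for
outlier detection, which is all the SQA needs. Scores come from a 30 × 30
SOM trained for 15,000 iterations (3,000 in the scaled-down test study) by
online competitive learning with a Gaussian neighbourhood; learning rate
(0.5) and radius (half the grid) decay as `p₀/(1 + 2t/T)`.

The QE → SQI map needs a threshold. Taken literally, "the 9th decile of all
SQI values" is circular (the SQI is defined from the threshold), so the
package uses the 90th percentile of the min–max-normalized QEs, which
matches the stated intent that roughly 90% of segments are high quality —
those all receive SQI 1, and quality falls linearly to 0 at the maximum
observed QE. All normalization constants and the threshold are frozen at
fit time, so scoring new data does not depend on the batch being scored; a
degenerate corpus (all QEs equal) scores SQI 1 everywhere.

## Refinement

Both filters are scalar with unit state transition. The cascade order
(fixed-noise smoothing first, adaptive re-filtering second) follows the
narrative order of the method; a `cascade = FALSE` switch filters the raw
series directly instead. The state initializes at the first measurement
with unit covariance, avoiding a startup transient. At SQI → 0 the
measurement noise `exp(1/SQI² − 1)` overflows double precision, so the SQI
is floored at 1e-3 and the exponent clamped at 700: `Rm ≈ 1e304` is finite
and the Kalman gain underflows to zero, which realizes the intended
"ignore this measurement" behaviour without NaNs. "More than three
consecutive low-quality segments" is read literally as runs of length ≥ 4
under a strict `SQI < 8th decile` test.

Estimate–truth pairing (needed only for evaluation) assigns each window the
ground-truth gap containing its reference time `window start + S_new/2`;
coverage is the percentage of emitted estimates retained. These conventions
are this package's own — the alignment of per-window estimates to annotated
beats is not fixed by the method description.

## Problem sizes and runtime

The test suite and the acceptance script run entirely on synthetic data at
deliberately moderate sizes: 60 s recordings for parameter recovery, one
5-minute corrupted recording for the quality study, VAE training scaled to
30 epochs and the SOM to 3,000 iterations there (the package defaults match
the full prescription: 100 epochs, 15,000 iterations). With these sizes the
whole study runs in minutes on one CPU while leaving the qualitative
comparisons (smoothing reduces RMSE; quality-adaptive refinement reduces
error at higher coverage than hard removal) clearly resolved.

## Known limitations

* The simulator's artifact model (additive broadband noise in fixed-length
  slots) makes corrupted segments nearly stationary; real artifacts are
  more varied, and the reported discrimination numbers should be read as a
  mechanism check, not a clinical operating point.
* Quality is assessed on the first 1.2 s of each analysis window (matching
  the resized second-pass window), while the first-pass ACF spans 3.75 s;
  an artifact late in the first-pass window can corrupt an estimate whose
  quality segment looks clean. This alignment is inherent to the method.
* The estimator assumes one dominant ACF peak per cardiac cycle; maternal
  heart interference and multi-peak morphologies are out of scope.
* With the unweighted VAE objective the latent partially collapses toward
  the prior on long training schedules; outlier detection still works, but
  the representation is not a general-purpose embedding.
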