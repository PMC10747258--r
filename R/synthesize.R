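#' Construct a Doppler ultrasound recording object
#'
#' A `dus_recording` is a tibble with one row per sample: columns `time`
#' (seconds), `amplitude` (arbitrary units) and `corrupted` (logical, marks
#' samples overwritten by an artifact episode). The sampling rate and the
#' optional ground-truth beat schedule travel as attributes.
#'
#' @param amplitude Numeric vector of samples; all values must be finite.
#' @param fs Sampling rate in Hz (positive).
#' @param schedule Optional [make_beat_schedule()] ground truth.
#' @param corrupted Optional logical vector marking artifact samples.
#' @return A tibble of class `dus_recording`.
#' @export
dus_recording <- function(amplitude, fs, schedule = NULL, corrupted = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive sampling rate in Hz.")
  }
  if (!all(is.finite(amplitude))) abort("all samples must be finite.")
  n <- length(amplitude)
  if (is.null(corrupted)) corrupted <- rep(FALSE, n)
  if (length(corrupted) != n) abort("`corrupted` must match the sample count.")
  out <- tibble(
    time = (seq_len(n) - 1L) / fs,
    amplitude = as.numeric(amplitude),
    corrupted = corrupted
  )
  class(out) <- c("dus_recording", class(out))
  attr(out, "fs") <- fs
  attr(out, "schedule") <- schedule
  out
}

#' @export
print.dus_recording <- function(x, ...) {
  fs <- attr(x, "fs")
  cat(sprintf(
    "<dus_recording> %.2f s at %g Hz (%d samples)%s%s\n",
    nrow(x) / fs, fs, nrow(x),
    if (!is.null(attr(x, "schedule"))) {
      sprintf(", %d annotated beats", nrow(attr(x, "schedule")))
    } else "",
    if (any(x$corrupted)) {
      sprintf(", %.1f%% corrupted", 100 * mean(x$corrupted))
    } else ""
  ))
  NextMethod()
}

#' Sampling rate of a recording or derived series
#'
#' @param x A `dus_recording` or `integrated_spectrum`.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(x) {
  fs <- attr(x, "fs") %||% attr(x, "source_fs")
  if (is.null(fs)) abort("object carries no sampling-rate attribute.")
  fs
}

#' Synthesize a Doppler ultrasound recording from a beat schedule
#'
#' Emulates the audio-band Doppler signature of fetal cardiac activity: each
#' beat contributes two short Gaussian-windowed tone bursts (valve opening and
#' closing events) with carrier frequencies inside the fetal cardiac band,
#' superimposed on a white Gaussian noise floor at a configurable
#' signal-to-noise ratio. Band-limited energy therefore peaks at the scheduled
#' beat times, which is the property the downstream autocorrelation estimator
#' relies on.
#'
#' @param schedule A [make_beat_schedule()] result; an empty schedule yields a
#'   pure noise-floor recording.
#' @param fs Sampling rate in Hz, at least 1000 so the 25-500 Hz band sits
#'   below Nyquist.
#' @param burst A list of burst-shape parameters:
#'   `width_s` Gaussian envelope standard deviation x 4 (approximate burst
#'   width, default 0.05 s), `carrier_lo`/`carrier_hi` carrier draw range in Hz
#'   (default 100-300), `second_offset_s` lag of the second (closing) burst
#'   (default 0.08 s), `second_gain` its relative amplitude (default 0.6).
#' @param snr_db Ratio of burst-train power to noise-floor power in dB
#'   (default 10).
#' @param seed Integer seed; the same seed reproduces the recording
#'   bit-for-bit.
#' @return A [dus_recording()] annotated with `schedule`.
#' @examples
#' sched <- make_beat_schedule(10, "constant", base_frri = 0.4)
#' rec <- synthesize_recording(sched, fs = 1000, seed = 1)
#' @export
synthesize_recording <- function(schedule,
                                 fs = 1000,
                                 burst = list(),
                                 snr_db = 10,
                                 seed = 1L) {
  if (fs < 1000) abort("`fs` must be >= 1000 Hz.")
  width_s <- burst$width_s %||% 0.05
  carrier_lo <- burst$carrier_lo %||% 100
  carrier_hi <- burst$carrier_hi %||% 300
  second_offset <- burst$second_offset_s %||% 0.08
  second_gain <- burst$second_gain %||% 0.6
  if (carrier_lo <= 0 || carrier_hi >= fs / 2) {
    abort("burst carriers must lie strictly inside (0, fs/2) Hz.")
  }

  duration <- attr(schedule, "duration") %||%
    (if (nrow(schedule)) max(schedule$beat_time) + 1 else 1)
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1L) / fs

  withr::with_seed(seed, {
    x <- numeric(n)
    sigma <- width_s / 4
    for (bt in schedule$beat_time) {
      for (ev in 1:2) {
        t0 <- bt + if (ev == 2L) second_offset else 0
        gain <- if (ev == 2L) second_gain else 1
        carrier <- runif(1, carrier_lo, carrier_hi)
        phase <- runif(1, 0, 2 * pi)
        lo <- max(1L, floor((t0 - 4 * sigma) * fs) + 1L)
        hi <- min(n, ceiling((t0 + 4 * sigma) * fs) + 1L)
        if (lo > n || hi < 1L) next
        idx <- lo:hi
        tl <- tt[idx] - t0
        x[idx] <- x[idx] +
          gain * exp(-tl^2 / (2 * sigma^2)) * sin(2 * pi * carrier * tl + phase)
      }
    }
    sig_power <- mean(x^2)
    noise_sd <- if (sig_power > 0) sqrt(sig_power / 10^(snr_db / 10)) else 1
    x <- x + rnorm(n, sd = noise_sd)
  })

  dus_recording(x, fs = fs, schedule = schedule)
}

#' Inject artifact episodes into a recording
#'
#' Overlays high-amplitude broadband noise on a chosen fraction of the
#' recording, in contiguous episodes, emulating maternal/fetal/probe movement
#' artifacts. The ground-truth beat schedule is preserved untouched; affected
#' samples are flagged in the `corrupted` column.
#'
#' @param rec A [dus_recording()].
#' @param fraction_corrupted Fraction of total duration to corrupt, in
#'   \[0, 1\].
#' @param episode_len Length of each artifact episode in seconds (default
#'   1.2 s, one quality-assessment segment).
#' @param noise_gain Artifact noise standard deviation as a multiple of the
#'   recording's RMS amplitude (default 5).
#' @param seed Integer seed controlling episode placement and noise.
#' @return A [dus_recording()] with updated `amplitude` and `corrupted`
#'   columns; `fraction_corrupted = 0` returns the input unchanged.
#' @export
corrupt_recording <- function(rec,
                              fraction_corrupted = 0.1,
                              episode_len = 1.2,
                              noise_gain = 5,
                              seed = 1L) {
  if (fraction_corrupted < 0 || fraction_corrupted > 1) {
    abort("`fraction_corrupted` must lie in [0, 1].")
  }
  if (episode_len <= 0) abort("`episode_len` must be positive.")
  if (fraction_corrupted == 0) return(rec)

  fs <- sampling_rate(rec)
  n <- nrow(rec)
  duration <- n / fs
  n_slots <- floor(duration / episode_len)
  n_epis <- max(1L, round(fraction_corrupted * duration / episode_len))
  n_epis <- min(n_epis, n_slots)
  ep_samp <- round(episode_len * fs)

  amplitude <- rec$amplitude
  corrupted <- rec$corrupted
  rms <- sqrt(mean(amplitude^2))

  withr::with_seed(seed, {
    slots <- sort(sample.int(n_slots, n_epis))
    for (s in slots) {
      idx <- ((s - 1L) * ep_samp + 1L):min(s * ep_samp, n)
      amplitude[idx] <- amplitude[idx] +
        rnorm(length(idx), sd = noise_gain * rms)
      corrupted[idx] <- TRUE
    }
  })

  dus_recording(amplitude, fs = fs,
                schedule = attr(rec, "schedule"), corrupted = corrupted)
}
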