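#' Zero-phase band-pass filter for the fetal cardiac band
#'
#' Fetal cardiac wall and valve motion modulates the Doppler audio signal
#' mostly below 500 Hz, while content under 25 Hz is dominated by gross
#' movement and equipment noise. A 4th-order Butterworth band-pass is applied
#' forward and backward ([signal::filtfilt()]), so the filter is zero-phase
#' and beat timing is not shifted.
#'
#' When `hi` equals the Nyquist frequency (the default 500 Hz at a 1 kHz
#' sampling rate) there is no content above the upper edge to remove and the
#' filter degenerates to a high-pass at `lo`; `hi` above Nyquist is an error.
#'
#' @param rec A [dus_recording()].
#' @param lo,hi Cutoff frequencies in Hz, `0 < lo < hi <= fs/2`.
#' @return A filtered [dus_recording()] of the same length.
#' @export
bandpass <- function(rec, lo = 25, hi = 500) {
  fs <- sampling_rate(rec)
  if (lo <= 0 || lo >= hi) abort("need 0 < lo < hi.")
  if (hi > fs / 2) abort("`hi` must not exceed the Nyquist frequency fs/2.")
  bf <- if (hi == fs / 2) {
    signal::butter(4, lo / (fs / 2), type = "high")
  } else {
    signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  }
  y <- signal::filtfilt(bf, rec$amplitude)
  dus_recording(y, fs = fs,
                schedule = attr(rec, "schedule"), corrupted = rec$corrupted)
}

#' Short-time Fourier transform power spectrogram
#'
#' Frames are Hann-windowed, centered on every `step`-th sample and
#' zero-padded at the edges, so the frame grid covers the whole recording and
#' frame timestamps coincide with sample times. The default 64 ms window with
#' a 1 ms step turns a 1 kHz recording into a spectrogram with one frame per
#' millisecond.
#'
#' @param rec A [dus_recording()].
#' @param window_len Analysis window length in seconds (default 0.064).
#' @param step Hop between frame centers in seconds (default 0.001).
#' @return A list of class `dus_spectrogram` with elements `power`
#'   (frequency-bin x frame matrix of magnitude-squared spectra),
#'   `freqs` (Hz), `frame_times` (s), `window_len`, `step`, `fs`.
#' @export
stft <- function(rec, window_len = 0.064, step = 0.001) {
  fs <- sampling_rate(rec)
  wl <- round(window_len * fs)
  hop <- round(step * fs)
  if (wl < 2L) abort("window must span at least 2 samples.")
  if (hop < 1L || hop >= wl) abort("need window_len > step > 0.")
  x <- rec$amplitude
  n <- length(x)
  if (n < wl) abort("recording is shorter than one analysis window.")

  centers <- seq(1L, n, by = hop)
  half <- wl %/% 2L
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(wl) / (wl + 1))  # Hann
  nbin <- wl %/% 2L + 1L
  xp <- c(numeric(half), x, numeric(wl))  # zero pad both edges

  power <- matrix(0, nrow = nbin, ncol = length(centers))
  chunk <- 20000L
  for (b0 in seq(1L, length(centers), by = chunk)) {
    cols <- b0:min(b0 + chunk - 1L, length(centers))
    starts <- centers[cols]  # padded coords: center - half + half = center
    idx <- outer(seq_len(wl) - 1L, starts, `+`)
    frames <- matrix(xp[idx], nrow = wl) * taper
    spec <- stats::mvfft(frames)[seq_len(nbin), , drop = FALSE]
    power[, cols] <- Mod(spec)^2
  }

  structure(
    list(
      power = power,
      freqs = (seq_len(nbin) - 1L) * fs / wl,
      frame_times = (centers - 1L) / fs,
      window_len = wl / fs,
      step = hop / fs,
      fs = fs
    ),
    class = "dus_spectrogram"
  )
}

#' @export
print.dus_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<dus_spectrogram> %d frames x %d bins, window %.0f ms, step %.0f ms\n",
    ncol(x$power), nrow(x$power), 1000 * x$window_len, 1000 * x$step
  ))
  invisible(x)
}

#' Integrate spectral power over a frequency band
#'
#' Collapses the spectrogram to a one-dimensional envelope by summing power
#' over all bins inside `[lo, hi]` Hz for each frame. The result, the
#' integrated spectrum, is the substrate of both the beat-interval estimator
#' and the quality-assessment network: cardiac bursts appear as sharp peaks.
#'
#' @param spec A [stft()] spectrogram.
#' @param lo,hi Band edges in Hz (default 25-500).
#' @return A tibble of class `integrated_spectrum` with columns `time` (s)
#'   and `power`, and attributes `step` and `source_fs`.
#' @export
integrate_spectrum <- function(spec, lo = 25, hi = 500) {
  keep <- spec$freqs >= lo & spec$freqs <= hi
  if (!any(keep)) abort("no spectrogram bins fall inside [lo, hi].")
  vals <- colSums(spec$power[keep, , drop = FALSE])
  integrated_spectrum(vals, times = spec$frame_times,
                      step = spec$step, source_fs = spec$fs)
}

#' @rdname integrate_spectrum
#' @param values Nonnegative per-frame band power.
#' @param times Frame timestamps in seconds (uniform spacing).
#' @param step Frame spacing in seconds.
#' @param source_fs Sampling rate of the originating recording, Hz.
#' @export
integrated_spectrum <- function(values, times = NULL, step = 0.001,
                                source_fs = NULL) {
  if (is.null(times)) times <- (seq_along(values) - 1L) * step
  out <- tibble(time = times, power = as.numeric(values))
  class(out) <- c("integrated_spectrum", class(out))
  attr(out, "step") <- step
  attr(out, "source_fs") <- source_fs
  out
}

#' Replace isolated spikes with the local median
#'
#' Electrical spikes in the integrated spectrum would masquerade as cardiac
#' events in the autocorrelation, so samples exceeding the rolling median by
#' more than `k` rolling MADs are replaced by that median. The rolling MAD is
#' computed as the rolling median of absolute deviations from the rolling
#' median (scaled by 1.4826), which keeps the detector robust to the spikes
#' it is hunting. The MAD is floored at 1% of the local median so that
#' noise-free stretches (where the MAD collapses to the curvature scale) do
#' not trip the detector on ordinary smooth variation.
#'
#' @param s An [integrated_spectrum()].
#' @param win Rolling window in frames; odd, at least 3 (default 51).
#' @param k Detection threshold in MAD units (default 5).
#' @return The despiked [integrated_spectrum()]; non-spike samples are
#'   untouched.
#' @export
remove_spikes <- function(s, win = 51L, k = 5) {
  if (win < 3L || win %% 2L == 0L) abort("`win` must be odd and >= 3.")
  x <- s$power
  if (length(x) < win) return(s)
  med <- runmed(x, win, endrule = "median")
  madv <- 1.4826 * runmed(abs(x - med), win, endrule = "median")
  madv <- pmax(madv, 0.01 * abs(med))
  spike <- x > med + k * madv
  x[spike] <- med[spike]
  integrated_spectrum(x, times = s$time, step = attr(s, "step"),
                      source_fs = attr(s, "source_fs"))
}

#' Full pre-processing chain: band-pass, STFT, band integration, despiking
#'
#' @inheritParams bandpass
#' @inheritParams stft
#' @param spike_win,spike_k Despiking parameters, see [remove_spikes()].
#' @return A despiked [integrated_spectrum()].
#' @examples
#' sched <- make_beat_schedule(10, "constant", base_frri = 0.4)
#' rec <- synthesize_recording(sched, seed = 1)
#' env <- preprocess(rec)
#' @export
preprocess <- function(rec, lo = 25, hi = 500,
                       window_len = 0.064, step = 0.001,
                       spike_win = 51L, spike_k = 5) {
  rec |>
    bandpass(lo = lo, hi = hi) |>
    stft(window_len = window_len, step = step) |>
    integrate_spectrum(lo = lo, hi = hi) |>
    remove_spikes(win = spike_win, k = spike_k)
}

#' Write / read an integrated spectrum as CSV (`time_s,value`)
#'
#' @param s An [integrated_spectrum()].
#' @param path File path.
#' @name integrated_io
#' @export
write_integrated_csv <- function(s, path) {
  utils::write.csv(data.frame(time_s = s$time, value = s$power), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname integrated_io
#' @export
read_integrated_csv <- function(path) {
  df <- utils::read.csv(path)
  step <- if (nrow(df) > 1L) median(diff(df$time_s)) else 0.001
  integrated_spectrum(df$value, times = df$time_s, step = step)
}
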