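#' Build a beat schedule with known beat-to-beat intervals
#'
#' A beat schedule is the ground truth of a simulated Doppler ultrasound
#' recording: a strictly ascending sequence of beat times whose successive
#' gaps are the true fetal RR intervals (FRRIs). Three interval patterns are
#' supported: a constant interval, a sinusoidally modulated interval
#' (emulating slow physiological heart-rate variation), and a piecewise
#' constant interval (step changes in rate).
#'
#' The first beat is placed at time 0 and beats are appended until the next
#' beat would fall at or beyond `duration`. For the sinusoidal pattern the
#' instantaneous interval at beat time `t` is
#' `base_frri + amp * sin(2 * pi * t / period)`; for the piecewise pattern
#' the interval is `modulation$values[i]` for `t >= modulation$times[i]`.
#'
#' @param duration Recording duration in seconds (positive).
#' @param pattern One of `"constant"`, `"sinusoidal"`, `"piecewise"`.
#' @param base_frri Baseline inter-beat interval in seconds. Must lie in
#'   \[0.25, 1.2\] s, the physiological fetal range (240 down to 50 bpm).
#' @param modulation For `"sinusoidal"`, a list with elements `amp` (seconds)
#'   and `period` (seconds); for `"piecewise"`, a list with `times` (ascending,
#'   starting at 0) and `values` (seconds, same length). Ignored for
#'   `"constant"`.
#' @param frri_lo,frri_hi Admissible interval range in seconds; a modulation
#'   that pushes any interval outside this range is rejected with an error.
#' @param seed Optional integer seed (the schedule itself is deterministic;
#'   the seed is recorded for provenance).
#'
#' @return A tibble of class `beat_schedule` with column `beat_time` (seconds)
#'   and attributes `pattern`, `base_frri`, `duration`.
#' @examples
#' sched <- make_beat_schedule(60, "constant", base_frri = 0.4)
#' nrow(sched) # 150 beats
#' range(diff(sched$beat_time))
#' @export
make_beat_schedule <- function(duration,
                               pattern = c("constant", "sinusoidal", "piecewise"),
                               base_frri = 0.4,
                               modulation = list(),
                               frri_lo = 0.25,
                               frri_hi = 1.2,
                               seed = NULL) {
  pattern <- match.arg(pattern)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    abort("`duration` must be a single positive number of seconds.")
  }
  if (base_frri < 0.25 || base_frri > 1.2) {
    abort("`base_frri` must lie in [0.25, 1.2] seconds.")
  }

  interval_at <- switch(pattern,
    constant = function(t) base_frri,
    sinusoidal = {
      amp <- modulation$amp %||% 0.05
      period <- modulation$period %||% 10
      if (period <= 0) abort("sinusoidal `period` must be positive.")
      function(t) base_frri + amp * sin(2 * pi * t / period)
    },
    piecewise = {
      times <- modulation$times
      values <- modulation$values
      if (is.null(times) || is.null(values) || length(times) != length(values)) {
        abort("piecewise modulation needs `times` and `values` of equal length.")
      }
      if (is.unsorted(times) || times[1] > 0) {
        abort("piecewise `times` must be ascending and start at or before 0.")
      }
      function(t) values[findInterval(t, times)]
    }
  )

  beat_times <- numeric(ceiling(duration / frri_lo) + 1L)
  t <- 0
  i <- 1L
  while (t < duration - 1e-9) {
    beat_times[i] <- t
    gap <- interval_at(t)
    if (gap < frri_lo || gap > frri_hi) {
      abort(sprintf(
        "modulated interval %.3f s at t = %.2f s falls outside [%.3f, %.3f] s.",
        gap, t, frri_lo, frri_hi
      ))
    }
    t <- t + gap
    i <- i + 1L
  }
  beat_times <- beat_times[seq_len(i - 1L)]

  out <- tibble(beat_time = beat_times)
  class(out) <- c("beat_schedule", class(out))
  attr(out, "pattern") <- pattern
  attr(out, "base_frri") <- base_frri
  attr(out, "duration") <- duration
  attr(out, "seed") <- seed
  out
}

#' True inter-beat interval containing each query time
#'
#' Looks up, for each time point, the ground-truth FRRI of the beat gap that
#' contains it. Query times before the first or after the last beat get `NA`.
#'
#' @param schedule A [make_beat_schedule()] result (or any tibble with a
#'   `beat_time` column).
#' @param at Numeric vector of query times in seconds.
#' @return Numeric vector of true intervals in seconds, `NA` outside the
#'   annotated span.
#' @export
true_frri_at <- function(schedule, at) {
  beats <- schedule$beat_time
  if (length(beats) < 2L) abort("schedule needs at least 2 beats.")
  gaps <- diff(beats)
  idx <- findInterval(at, beats)
  out <- rep(NA_real_, length(at))
  ok <- idx >= 1L & idx <= length(gaps)
  out[ok] <- gaps[idx[ok]]
  out
}
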