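#' Search configuration for double-autocorrelation interval estimation
#'
#' @param S First-pass analysis window in seconds (default 3.75 s, the window
#'   standard in computerized fetal non-stress testing).
#' @param frri_min,frri_max Admissible beat-interval range in seconds
#'   (defaults 0.25 and 1.2 s, i.e. 240 down to 50 bpm, bracketing the
#'   physiological fetal range).
#' @param range Half-width of the second-pass refinement search around the
#'   approximate interval, in seconds (default 0.1 s).
#' @param delta_factor The second-pass window is
#'   `S_new = 2 * frri_app + delta_factor * frri_app`; the default 0.5 makes
#'   the margin half an interval, so the window spans two beats plus slack.
#' @param alpha Harmonic-rejection acceptance ratio, see [resolve_harmonic()].
#' @return A list of class `frri_config`.
#' @export
frri_config <- function(S = 3.75, frri_min = 0.25, frri_max = 1.2,
                        range = 0.1, delta_factor = 0.5, alpha = 0.75) {
  if (!(frri_min > 0 && frri_min < frri_max && frri_max < S)) {
    abort("need 0 < frri_min < frri_max < S.")
  }
  if (range <= 0) abort("`range` must be positive.")
  structure(
    list(S = S, frri_min = frri_min, frri_max = frri_max,
         range = range, delta_factor = delta_factor, alpha = alpha),
    class = "frri_config"
  )
}

seg_values <- function(s, t0, len, step) {
  i0 <- round(t0 / step) + 1L
  i1 <- i0 + round(len / step) - 1L
  if (i0 < 1L || i1 > nrow(s)) abort("window extends beyond the series.")
  s$power[i0:i1]
}

#' Estimate one window's beat interval with two autocorrelation passes
#'
#' Pass 1 computes the autocorrelation of the `S`-second segment starting at
#' `t0` and finds the dominant non-harmonic peak inside
#' `[frri_min, frri_max]`; its lag is the approximate interval `frri_app`.
#' The window is then resized to `S_new = 2.5 * frri_app` (two beats plus
#' half-a-beat slack), anchored at the same `t0`, and a second
#' autocorrelation restricted to `frri_app +/- range` yields the refined
#' estimate `frri_est`. If either pass finds no peak the window is flagged
#' `ok = FALSE` and the estimate is carried as `frri_app` (or `NA` when even
#' pass 1 failed).
#'
#' @param s An [integrated_spectrum()].
#' @param t0 Window start in seconds; `[t0, t0 + S]` must lie inside the
#'   series.
#' @param cfg A [frri_config()].
#' @return A one-row tibble: `window_start`, `frri_app`, `s_new`, `frri_est`,
#'   `ok`.
#' @export
estimate_window <- function(s, t0, cfg = frri_config()) {
  step <- attr(s, "step")
  y1 <- seg_values(s, t0, cfg$S, step)
  max_lag1 <- min(length(y1) - 1L, round(cfg$frri_max / step) + 2L)

  fail <- function(app, s_new) {
    tibble(window_start = t0, frri_app = app, s_new = s_new,
           frri_est = app, ok = FALSE)
  }
  if (sd(y1) == 0) return(fail(NA_real_, NA_real_))

  a1 <- acf_series(y1, max_lag = max_lag1, step = step)
  p1 <- find_max_peak(a1, cfg$frri_min, cfg$frri_max)
  if (is.na(p1)) return(fail(NA_real_, NA_real_))
  frri_app <- resolve_harmonic(a1, p1, cfg$frri_min, cfg$frri_max,
                               alpha = cfg$alpha, tol = cfg$range / 2)

  s_new <- (2 + cfg$delta_factor) * frri_app
  y2 <- seg_values(s, t0, min(s_new, cfg$S), step)
  lo2 <- max(frri_app - cfg$range, cfg$frri_min)
  hi2 <- min(frri_app + cfg$range, cfg$frri_max)
  max_lag2 <- min(length(y2) - 1L, round(hi2 / step) + 2L)
  if (sd(y2) == 0) return(fail(frri_app, s_new))
  a2 <- acf_series(y2, max_lag = max_lag2, step = step)
  p2 <- find_max_peak(a2, lo2, hi2)
  if (is.na(p2)) return(fail(frri_app, s_new))
  frri_est <- resolve_harmonic(a2, p2, lo2, hi2,
                               alpha = cfg$alpha, tol = cfg$range / 2)

  tibble(window_start = t0, frri_app = frri_app, s_new = s_new,
         frri_est = frri_est, ok = TRUE)
}

#' Track beat intervals across a recording
#'
#' Applies [estimate_window()] sequentially. After each window the start
#' advances by half the refined interval (`frri_est / 2`; falling back to
#' `frri_app / 2`, then `S / 2`, when a pass failed), and the analysis window
#' is re-initialized to the full `S` for the next estimate. Tracking stops
#' when the `S`-window no longer fits inside the series.
#'
#' @inheritParams estimate_window
#' @return A tibble with one row per window: `window_start`, `frri_app`,
#'   `s_new`, `frri_est`, `ok`.
#' @examples
#' sched <- make_beat_schedule(20, "constant", base_frri = 0.4)
#' env <- preprocess(synthesize_recording(sched, seed = 1))
#' est <- track_frri(env)
#' @export
track_frri <- function(s, cfg = frri_config()) {
  step <- attr(s, "step")
  t_end <- (nrow(s) - 1L) * step
  if (t_end < cfg$S) abort("series is shorter than one analysis window.")
  out <- vector("list", ceiling(t_end / (cfg$frri_min / 2)) + 1L)
  t0 <- 0
  i <- 0L
  while (t0 + cfg$S <= t_end + step / 2) {
    est <- estimate_window(s, t0, cfg)
    i <- i + 1L
    out[[i]] <- est
    shift <- if (est$ok) {
      est$frri_est / 2
    } else if (!is.na(est$frri_app)) {
      est$frri_app / 2
    } else {
      cfg$S / 2
    }
    t0 <- t0 + shift
  }
  dplyr::bind_rows(out[seq_len(i)])
}

#' Write / read beat-interval estimates as CSV
#'
#' Columns: `window_start_s,frri_app_s,frri_est_s,s_new_s,ok`.
#'
#' @param estimates A [track_frri()] tibble.
#' @param path File path.
#' @name frri_io
#' @export
write_frri_csv <- function(estimates, path) {
  utils::write.csv(
    data.frame(window_start_s = estimates$window_start,
               frri_app_s = estimates$frri_app,
               frri_est_s = estimates$frri_est,
               s_new_s = estimates$s_new,
               ok = estimates$ok),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname frri_io
#' @export
read_frri_csv <- function(path) {
  df <- utils::read.csv(path)
  tibble(window_start = df$window_start_s, frri_app = df$frri_app_s,
         s_new = df$s_new_s, frri_est = df$frri_est_s, ok = df$ok)
}
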