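#' Quality-adaptive measurement-noise covariance
#'
#' Inflates the scalar measurement-noise covariance as quality drops:
#' \deqn{R_m = R_0 \, e^{1/SQI_m^2 - 1}.}
#' At SQI 1 the measurement is fully trusted (`Rm = R0`); as SQI approaches 0
#' the covariance grows without bound and the Kalman gain collapses to zero,
#' so the filter coasts on its prediction. The SQI is floored at `floor` and
#' the exponent is clamped at 700 so `Rm` stays a finite (astronomically
#' large) double.
#'
#' @param sqi Signal-quality indices in \[0, 1\].
#' @param R0 Baseline measurement-noise covariance (positive, default 1).
#' @param floor Smallest SQI used in the formula (default 1e-3).
#' @return Covariances `Rm >= R0`, with equality iff `sqi = 1`.
#' @examples
#' adapt_R(1)           # 1
#' adapt_R(1 / sqrt(2)) # e
#' @export
adapt_R <- function(sqi, R0 = 1, floor = 1e-3) {
  if (R0 <= 0) abort("`R0` must be positive.")
  R0 * exp(pmin(1 / pmax(sqi, floor)^2 - 1, 700))
}

#' Scalar Kalman filter with unit state transition
#'
#' The beat-interval series is modelled as a first-order autoregressive
#' process with unit transition: the predicted state is the previous
#' estimate, with process noise variance `Q0`. Each step runs
#' predict (`x_pred = x`, `P_pred = P + Q0`), gain
#' (`K = P_pred / (P_pred + Rm)`) and update
#' (`x = x_pred + K (z - x_pred)`, `P = (1 - K) P_pred`).
#'
#' @param z Measurement series (beat intervals in seconds).
#' @param R0 Measurement-noise covariance used when `R_series` is absent.
#' @param Q0 Process-noise covariance.
#' @param x0 Initial state (default: the first measurement, avoiding a
#'   transient).
#' @param P0 Initial state covariance (default 1).
#' @param R_series Optional per-step measurement-noise covariances (e.g. from
#'   [adapt_R()]), recycled against `z`.
#' @return Filtered series, same length as `z`.
#' @export
kalman_filter <- function(z, R0 = 1, Q0 = 0.1, x0 = z[1], P0 = 1,
                          R_series = NULL) {
  n <- length(z)
  if (n == 0L) abort("empty measurement series.")
  if (is.null(R_series)) R_series <- rep(R0, n)
  if (length(R_series) != n) abort("`R_series` must match `z` in length.")
  out <- numeric(n)
  x <- x0
  p <- P0
  for (m in seq_len(n)) {
    p_pred <- p + Q0
    k <- p_pred / (p_pred + R_series[m])
    x <- x + k * (z[m] - x)
    p <- (1 - k) * p_pred
    out[m] <- x
  }
  out
}

#' Flag estimates from long runs of low-quality segments
#'
#' A segment is low quality when its SQI is strictly below the
#' `quantile`-quantile (default the 8th decile) of all SQIs in the series.
#' Estimates inside a maximal run of at least `run_len` consecutive
#' low-quality segments (default 4, i.e. "more than three") are flagged for
#' discarding; shorter runs are kept because the adaptive filter can still
#' correct them.
#'
#' @param sqi Signal-quality indices.
#' @param quantile Quantile defining the low-quality threshold (default 0.8).
#' @param run_len Minimum run length that triggers discarding (default 4).
#' @return Logical `kept` flags, same length as `sqi`.
#' @examples
#' discard_runs(c(1, 1, 0.1, 0.1, 0.1, 0.1, 1)) # T T F F F F T
#' @export
discard_runs <- function(sqi, quantile = 0.8, run_len = 4L) {
  if (!length(sqi)) abort("empty SQI series.")
  thr <- unname(stats::quantile(sqi, quantile))
  low <- sqi < thr
  r <- rle(low)
  drop_run <- r$values & r$lengths >= run_len
  !rep(drop_run, r$lengths)
}

#' Refine beat-interval estimates with the two-stage Kalman cascade
#'
#' Stage 1 smooths the raw estimates with a conventional fixed-noise Kalman
#' filter (`R0 = 1`, `Q0 = 0.1`). Stage 2 re-filters the smoothed series with
#' the quality-adaptive filter (`R0 = 1`, `Q0 = 1`, `Rm` from [adapt_R()]),
#' so estimates from low-quality segments are pulled toward the prediction.
#' Finally estimates from runs of at least four consecutive low-quality
#' segments are flagged as discarded.
#'
#' Windows whose first autocorrelation pass produced no estimate at all
#' (`frri_est` is `NA`) are dropped before filtering: they carry no
#' measurement.
#'
#' @param estimates A [track_frri()] tibble with an `sqi` column (see
#'   [align_sqi()]), or separate `estimates` and `sqi` arguments.
#' @param sqi Optional SQI vector aligned with `estimates` rows.
#' @param R0_1,Q0_1 Stage-1 filter covariances (defaults 1, 0.1).
#' @param R0_2,Q0_2 Stage-2 filter covariances (defaults 1, 1).
#' @param sqi_floor Floor for [adapt_R()] (default 1e-3).
#' @param discard_quantile,discard_run_len Discard-rule settings, see
#'   [discard_runs()].
#' @param cascade If `TRUE` (default) stage 2 consumes stage-1 output; if
#'   `FALSE` both stages filter the raw series independently and stage 2 is
#'   reported.
#' @return A tibble of class `refined_trace`: `time` (window start),
#'   `s_new`, `frri_raw`, `frri_kf1`, `frri_kf2`, `sqi`, `kept`.
#' @export
refine_frri <- function(estimates, sqi = NULL,
                        R0_1 = 1, Q0_1 = 0.1, R0_2 = 1, Q0_2 = 1,
                        sqi_floor = 1e-3,
                        discard_quantile = 0.8, discard_run_len = 4L,
                        cascade = TRUE) {
  if (is.null(sqi)) {
    if (!"sqi" %in% names(estimates)) {
      abort("provide `sqi` or an estimates table with an `sqi` column.")
    }
    sqi <- estimates$sqi
  }
  if (length(sqi) != nrow(estimates)) {
    abort("`sqi` length must match the number of estimates.")
  }
  ok <- !is.na(estimates$frri_est)
  est <- estimates[ok, , drop = FALSE]
  sqi <- sqi[ok]
  if (!nrow(est)) abort("no usable estimates to refine.")

  z <- est$frri_est
  kf1 <- kalman_filter(z, R0 = R0_1, Q0 = Q0_1)
  stage2_in <- if (cascade) kf1 else z
  kf2 <- kalman_filter(stage2_in, R0 = R0_2, Q0 = Q0_2,
                       R_series = adapt_R(sqi, R0 = R0_2, floor = sqi_floor))
  kept <- discard_runs(sqi, quantile = discard_quantile,
                       run_len = discard_run_len)

  out <- tibble(
    time = est$window_start,
    s_new = est$s_new,
    frri_raw = z,
    frri_kf1 = kf1,
    frri_kf2 = kf2,
    sqi = sqi,
    kept = kept
  )
  class(out) <- c("refined_trace", class(out))
  out
}

#' Write / read a refined trace as CSV
#'
#' Columns: `time_s,frri_raw_s,frri_refined_s,sqi,kept`.
#'
#' @param trace A [refine_frri()] tibble.
#' @param path File path.
#' @name refined_io
#' @export
write_refined_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace$time, frri_raw_s = trace$frri_raw,
               frri_refined_s = trace$frri_kf2, sqi = trace$sqi,
               kept = trace$kept),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
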