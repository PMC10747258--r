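#' Convert between beat intervals and heart rate
#'
#' `FHR = 60 / FRRI` with the interval in seconds (equivalently
#' `60 * Fs / FRRI_samples` when the interval is counted in samples at rate
#' `Fs`).
#'
#' @param frri Beat intervals in seconds (positive).
#' @param fhr Heart rates in beats per minute (positive).
#' @return `frri_to_fhr()`: bpm; `fhr_to_frri()`: seconds.
#' @examples
#' frri_to_fhr(0.5) # 120 bpm
#' frri_to_fhr(0.4) # 150 bpm
#' @export
frri_to_fhr <- function(frri) {
  if (any(frri <= 0, na.rm = TRUE)) abort("intervals must be positive.")
  60 / frri
}

#' @rdname frri_to_fhr
#' @export
fhr_to_frri <- function(fhr) {
  if (any(fhr <= 0, na.rm = TRUE)) abort("heart rates must be positive.")
  60 / fhr
}

#' Normalized absolute error of an interval estimate
#'
#' `|est - true| / true`; values above 0.03 are used as a proxy label for a
#' low-quality segment when no expert annotation exists.
#'
#' @param frri_est,frri_true Estimated and true intervals in seconds.
#' @return Dimensionless errors.
#' @examples
#' nae(0.412, 0.4) # 0.03
#' @export
nae <- function(frri_est, frri_true) {
  if (any(frri_true <= 0)) abort("true intervals must be positive.")
  abs(frri_est - frri_true) / frri_true
}

#' Pair interval estimates with ground-truth beat gaps
#'
#' Each window's reference time is its start plus half its (resized) analysis
#' window, `window_start + s_new / 2`; the ground truth is the inter-beat gap
#' containing that reference time. Only kept estimates are paired; reference
#' times outside the annotated span are dropped.
#'
#' @param trace A [refine_frri()] tibble (or any tibble with `time`, `s_new`,
#'   `kept` and an estimate column).
#' @param schedule The ground-truth [make_beat_schedule()].
#' @param estimate Name of the estimate column to evaluate (default
#'   `"frri_kf2"`).
#' @return A tibble `time`, `frri_est`, `frri_true`.
#' @export
pair_with_truth <- function(trace, schedule, estimate = "frri_kf2") {
  if (nrow(schedule) < 2L) abort("schedule needs at least 2 beats.")
  kept <- trace[trace$kept, , drop = FALSE]
  if (!nrow(kept)) {
    return(tibble(time = numeric(), frri_est = numeric(),
                  frri_true = numeric()))
  }
  s_new <- kept$s_new
  s_new[is.na(s_new)] <- mean(s_new, na.rm = TRUE)
  ref <- kept$time + s_new / 2
  truth <- true_frri_at(schedule, ref)
  ok <- !is.na(truth)
  tibble(time = ref[ok], frri_est = kept[[estimate]][ok],
         frri_true = truth[ok])
}

#' Accuracy and coverage metrics for an interval trace
#'
#' RMSE is computed on the intervals in milliseconds,
#' \eqn{\sqrt{\frac1\Gamma\sum_i (\hat{FRRI}_i - FRRI_i)^2}}; AAE on the
#' corresponding heart rates in bpm,
#' \eqn{\frac1\Gamma\sum_i |\hat{FHR}_i - FHR_i|}; coverage is the percentage
#' of emitted estimates that were retained.
#'
#' @param pairs A [pair_with_truth()] tibble.
#' @param total_estimates Denominator for coverage: the number of estimates
#'   the tracker emitted (kept or not).
#' @param n_kept Number of retained estimates (default `nrow(pairs)`).
#' @return A one-row tibble `rmse_ms`, `aae_bpm`, `coverage_pct`, `n_pairs`;
#'   error metrics are `NA` when no pairs exist.
#' @examples
#' p <- tibble::tibble(time = 1:2, frri_est = c(0.5, 0.51),
#'                     frri_true = c(0.5, 0.5))
#' fhr_metrics(p, total_estimates = 2)
#' @export
fhr_metrics <- function(pairs, total_estimates, n_kept = nrow(pairs)) {
  if (nrow(pairs)) {
    err_s <- pairs$frri_est - pairs$frri_true
    rmse_ms <- sqrt(mean(err_s^2)) * 1000
    aae_bpm <- mean(abs(frri_to_fhr(pairs$frri_est) -
                          frri_to_fhr(pairs$frri_true)))
  } else {
    rmse_ms <- NA_real_
    aae_bpm <- NA_real_
  }
  tibble(
    rmse_ms = rmse_ms,
    aae_bpm = aae_bpm,
    coverage_pct = 100 * n_kept / total_estimates,
    n_pairs = nrow(pairs)
  )
}

#' Run the scenario comparison harness on an annotated recording
#'
#' Shares one pre-processing pass, one beat-interval tracking pass and one
#' fitted quality model across four scenarios and reports their metrics:
#'
#' * `raw`: rough double-autocorrelation estimates, nothing discarded;
#' * `remove_low_sqi`: every estimate whose SQI falls strictly below the 8th
#'   decile of all SQIs is discarded;
#' * `conventional_kf`: fixed-noise Kalman smoothing only, nothing discarded;
#' * `proposed`: the full cascade (fixed filter, adaptive filter, long
#'   low-quality runs discarded).
#'
#' @param rec An annotated [dus_recording()] (its `schedule` attribute is the
#'   ground truth).
#' @param cfg A [frri_config()].
#' @param vae_cfg A [vae_config()].
#' @param som_iterations,som_grid Self-organizing-map settings.
#' @param sqa A pre-fitted [sqa_fit()] model to reuse; if `NULL`, one is
#'   fitted on this recording's segments.
#' @return A list with `metrics` (one row per scenario), `trace` (the refined
#'   trace), `estimates`, `scores` and `sqa` (the fitted quality model).
#' @export
run_scenarios <- function(rec, cfg = frri_config(), vae_cfg = vae_config(),
                          som_iterations = 15000L, som_grid = c(30L, 30L),
                          sqa = NULL) {
  schedule <- attr(rec, "schedule")
  if (is.null(schedule)) abort("recording carries no ground-truth schedule.")

  env <- preprocess(rec)
  est <- track_frri(env, cfg)
  segs <- segment_for_sqa(env, est$window_start)
  if (is.null(sqa)) {
    sqa <- sqa_fit(segs, vae_cfg = vae_cfg, som_grid = som_grid,
                   som_iterations = som_iterations)
    scores <- sqa$train_scores
  } else {
    scores <- sqa_score(sqa, segs)
  }
  est_sqi <- align_sqi(est, scores)
  trace <- refine_frri(est_sqi)
  total <- nrow(trace)  # estimates the tracker emitted (with a measurement)

  scen <- function(name, estimate, kept) {
    tr <- trace
    tr$kept <- kept
    pairs <- pair_with_truth(tr, schedule, estimate = estimate)
    dplyr::bind_cols(tibble(scenario = name),
                     fhr_metrics(pairs, total, n_kept = sum(kept)))
  }
  low <- trace$sqi < unname(quantile(trace$sqi, 0.8))
  metrics <- dplyr::bind_rows(
    scen("raw", "frri_raw", rep(TRUE, total)),
    scen("remove_low_sqi", "frri_raw", !low),
    scen("conventional_kf", "frri_kf1", rep(TRUE, total)),
    scen("proposed", "frri_kf2", trace$kept)
  )
  list(metrics = metrics, trace = trace, estimates = est_sqi,
       scores = scores, sqa = sqa)
}
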