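#' Cut quality-assessment segments from the integrated spectrum
#'
#' One segment is cut per beat-interval analysis window, aligned to the
#' window's start, with a fixed span of 1.2 s (the typical size of the
#' resized second-pass window), and linearly resampled to 1024 samples with
#' endpoints preserved. Segments whose span would extend past the end of the
#' series are skipped with a warning; their windows later inherit the quality
#' score of the nearest preceding segment.
#'
#' @param s An [integrated_spectrum()].
#' @param starts Segment start times in seconds (typically
#'   `track_frri(s)$window_start`).
#' @param win Segment span in seconds (default 1.2).
#' @param len Resampled length (default 1024).
#' @return A tibble of class `sqa_segments` with columns `start` (s) and `x`
#'   (list-column of length-`len` vectors).
#' @export
segment_for_sqa <- function(s, starts, win = 1.2, len = 1024L) {
  if (win <= 0) abort("`win` must be positive.")
  step <- attr(s, "step")
  t_end <- s$time[nrow(s)]
  keep <- starts + win <= t_end + step / 2
  if (any(!keep)) {
    warn(sprintf("%d segment(s) extend past the series end and were skipped.",
                 sum(!keep)))
  }
  starts <- starts[keep]
  xs <- lapply(starts, function(t0) {
    i0 <- round(t0 / step) + 1L
    i1 <- min(i0 + round(win / step) - 1L, nrow(s))
    seg <- s$power[i0:i1]
    approx(seq_along(seg), seg, n = len)$y
  })
  out <- tibble(start = starts, x = xs)
  class(out) <- c("sqa_segments", class(out))
  attr(out, "win") <- win
  out
}

#' Combined signal-quality index from quantization errors
#'
#' Quantization errors are min-max normalized to \[0, 1\] and compared to a
#' threshold `th`, the `th_quantile` quantile (default the 9th decile) of the
#' normalized errors: segments at or below `th` get SQI 1, and above it the
#' SQI falls linearly to 0 at normalized error 1,
#' \deqn{SQI = 1 \ \mathrm{if}\ \tilde{QE} \le th,\quad
#'       1 - \frac{\tilde{QE} - th}{1 - th} \ \mathrm{otherwise}.}
#' The default threshold encodes the working assumption that roughly 90% of
#' segments are of high quality, so low quality is an outlier property. If
#' all errors are equal (degenerate normalization) every segment scores 1.
#'
#' @param qes Nonnegative quantization errors.
#' @param th_quantile Quantile defining the full-quality threshold
#'   (default 0.9).
#' @param stats Optional frozen normalization list with elements `qe_min`,
#'   `qe_max`, `th` (from a fitted [sqa_fit()] model); when supplied, new
#'   errors are scored against the training-corpus scale instead of their
#'   own.
#' @return A tibble with columns `qe`, `qe_norm` and `sqi`.
#' @examples
#' combined_sqi(c(2, 4, 6))$qe_norm # 0, 0.5, 1
#' @export
combined_sqi <- function(qes, th_quantile = 0.9, stats = NULL) {
  if (is.null(stats)) {
    qe_min <- min(qes)
    qe_max <- max(qes)
    rng <- qe_max - qe_min
    qe_norm <- if (rng > 0) (qes - qe_min) / rng else rep(0, length(qes))
    th <- unname(quantile(qe_norm, th_quantile))
  } else {
    rng <- stats$qe_max - stats$qe_min
    qe_norm <- if (rng > 0) (qes - stats$qe_min) / rng else rep(0, length(qes))
    qe_norm <- pmin(pmax(qe_norm, 0), 1)
    th <- stats$th
  }
  sqi <- ifelse(qe_norm <= th, 1,
                if (th < 1) 1 - (qe_norm - th) / (1 - th) else 1)
  tibble(qe = qes, qe_norm = qe_norm, sqi = pmin(pmax(sqi, 0), 1))
}

#' Fit the full signal-quality model (VAE + SOM + SQI calibration)
#'
#' Trains the variational autoencoder on the segments, encodes them to their
#' latent means, trains the self-organizing map on those means, computes the
#' training-corpus quantization errors, and freezes the min-max normalization
#' constants and the SQI threshold so that new data can be scored on the same
#' scale.
#'
#' @param segments A [segment_for_sqa()] tibble.
#' @param vae_cfg A [vae_config()].
#' @param som_grid,som_iterations,som_seed Self-organizing-map settings
#'   (defaults 30 x 30 grid, 15000 iterations).
#' @param th_quantile Quantile for the full-quality threshold (default 0.9).
#' @return An object of class `sqa_model` with elements `vae`, `som`,
#'   `stats` (frozen `qe_min`, `qe_max`, `th`) and `train_scores` (the
#'   training-corpus [combined_sqi()] table with segment starts).
#' @export
sqa_fit <- function(segments, vae_cfg = vae_config(),
                    som_grid = c(30L, 30L), som_iterations = 15000L,
                    som_seed = vae_cfg$seed, th_quantile = 0.9) {
  vae <- train_vae(segments, vae_cfg)
  mu <- vae_encode(vae, segments)$mu
  som <- train_som(mu, grid = som_grid, iterations = som_iterations,
                   seed = som_seed)
  qe <- quantization_error(som, mu)
  base <- combined_sqi(qe, th_quantile = th_quantile)
  stats <- list(qe_min = min(qe), qe_max = max(qe),
                th = unname(quantile(base$qe_norm, th_quantile)))
  train_scores <- dplyr::bind_cols(tibble(start = segments$start), base)
  structure(
    list(vae = vae, som = som, stats = stats, th_quantile = th_quantile,
         train_scores = train_scores),
    class = "sqa_model"
  )
}

#' Score segments with a fitted signal-quality model
#'
#' @param model An [sqa_fit()] model.
#' @param segments A [segment_for_sqa()] tibble.
#' @return A tibble `start`, `qe`, `qe_norm`, `sqi`.
#' @export
sqa_score <- function(model, segments) {
  mu <- vae_encode(model$vae, segments)$mu
  qe <- quantization_error(model$som, mu)
  dplyr::bind_cols(
    tibble(start = segments$start),
    combined_sqi(qe, stats = model$stats)
  )
}

#' @export
print.sqa_model <- function(x, ...) {
  cat(sprintf(
    "<sqa_model> VAE(latent %d) + SOM(%d x %d); th = %.3f on normalized QE\n",
    x$vae$cfg$latent_dim, x$som$grid[1], x$som$grid[2], x$stats$th
  ))
  invisible(x)
}

#' Attach segment quality scores to beat-interval windows
#'
#' Each analysis window takes the SQI of the quality segment sharing its
#' start time; windows whose segment was skipped (tail of the recording)
#' inherit the nearest preceding segment's score.
#'
#' @param estimates A [track_frri()] tibble.
#' @param scores An [sqa_score()] (or `train_scores`) tibble.
#' @return `estimates` with an `sqi` column appended.
#' @export
align_sqi <- function(estimates, scores) {
  if (nrow(scores) == 0L) abort("no quality scores to align.")
  idx <- findInterval(estimates$window_start + 1e-9, scores$start)
  idx[idx < 1L] <- 1L
  dplyr::mutate(estimates, sqi = scores$sqi[idx])
}
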