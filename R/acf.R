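#' Normalized autocorrelation of a series
#'
#' For a series \eqn{Y_1,\dots,Y_N} the autocorrelation at lag \eqn{k} is
#' \deqn{acf_k = \frac{\sum_{i=1}^{N-k}(Y_i-\bar Y)(Y_{i+k}-\bar Y)}
#'                    {\sum_{i=1}^{N}(Y_i-\bar Y)^2},}
#' i.e. the lagged cross-products of the mean-centred series divided by its
#' total sum of squares. The numerator is evaluated exactly via a zero-padded
#' FFT (linear, not circular, correlation); a brute-force double loop gives
#' identical values up to floating-point rounding and serves as the test
#' oracle. `acf_0` is always 1 and \eqn{|acf_k|\le 1} by Cauchy-Schwarz.
#'
#' @param y Numeric series of length at least 2; a constant series has a zero
#'   denominator and is rejected as degenerate.
#' @param max_lag Largest lag, in samples (default `length(y) - 1`).
#' @param step Sample spacing in seconds, used to express lags in seconds
#'   (default 1, i.e. lags in samples).
#' @return A tibble of class `acf_series` with columns `lag` (seconds) and
#'   `value`.
#' @examples
#' acf_series(c(1, 2, 3, 4))$value[2] # 0.25
#' @export
acf_series <- function(y, max_lag = length(y) - 1L, step = 1) {
  n <- length(y)
  if (n < 2L) abort("series must have length >= 2.")
  max_lag <- min(max_lag, n - 1L)
  yc <- y - mean(y)
  denom <- sum(yc^2)
  if (denom <= 0) abort("constant series: autocorrelation is undefined.")
  m <- stats::nextn(2L * n, 2)
  f <- fft(c(yc, numeric(m - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(max_lag + 1L)] / m
  out <- tibble(lag = (0:max_lag) * step, value = ac / denom)
  class(out) <- c("acf_series", class(out))
  attr(out, "step") <- step
  out
}

#' Highest autocorrelation peak inside a lag range
#'
#' A peak is a local maximum strictly greater than both neighbours. The lag of
#' the highest peak with `lo <= lag <= hi` is returned; ties are broken toward
#' the smaller lag (favouring the fundamental over harmonics). `NA` signals
#' that the window contains no peak and its estimate is unreliable.
#'
#' @param a An [acf_series()].
#' @param lo,hi Search range in seconds, `lo < hi`.
#' @return Peak lag in seconds, or `NA_real_` if no local maximum exists in
#'   the range.
#' @export
find_max_peak <- function(a, lo, hi) {
  if (lo >= hi) abort("need lo < hi.")
  v <- a$value
  lags <- a$lag
  n <- length(v)
  if (n < 3L) return(NA_real_)
  i <- 2:(n - 1L)
  is_peak <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  cand <- i[is_peak & lags[i] >= lo & lags[i] <= hi]
  if (!length(cand)) return(NA_real_)
  best <- cand[which.max(v[cand])]  # which.max takes the first (smallest lag)
  lags[best]
}

#' Reject harmonic peaks in favour of the fundamental
#'
#' An autocorrelation peak at twice the true beat interval is a harmonic. If a
#' local maximum exists near half the detected lag (within `tol` seconds) and
#' its autocorrelation is at least `alpha` times the detected peak's value,
#' the sub-multiple is taken instead; the check recurses until no acceptable
#' sub-multiple remains.
#'
#' @param a An [acf_series()].
#' @param peak Lag (s) returned by [find_max_peak()].
#' @param lo,hi Admissible lag range in seconds.
#' @param alpha Acceptance ratio for the sub-multiple peak value
#'   (default 0.75).
#' @param tol Search half-width around `peak / 2` in seconds (default 0.05,
#'   half the refinement `range`).
#' @return The resolved fundamental lag in seconds.
#' @export
resolve_harmonic <- function(a, peak, lo, hi, alpha = 0.75, tol = 0.05) {
  if (is.na(peak)) return(peak)
  v <- a$value
  lags <- a$lag
  n <- length(v)
  i <- 2:(n - 1L)
  is_peak <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  peak_idx <- i[is_peak]
  peak_val_at <- function(lag) v[which.min(abs(lags - lag))]
  repeat {
    half <- peak / 2
    if (half < lo) break
    cand <- peak_idx[abs(lags[peak_idx] - half) <= tol &
                       lags[peak_idx] >= lo & lags[peak_idx] <= hi]
    if (!length(cand)) break
    best <- cand[which.max(v[cand])]
    if (v[best] >= alpha * peak_val_at(peak)) peak <- lags[best] else break
  }
  peak
}
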