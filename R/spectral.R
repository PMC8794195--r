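#' Windowed spectral density of a daily series
#'
#' The mean is removed, the series is tapered (Hann by default, Hamming
#' optional), zero-padded to the next power of two and Fourier
#' transformed; the spectral density at each positive frequency is
#' psi_f = a_f^2 + b_f^2 from the real and imaginary components. The
#' zero-frequency term is excluded. Frequencies are in cycles per sample
#' (cycles per day for daily series), on (0, 0.5].
#'
#' A constant input has a zero spectrum and is returned with a warning.
#'
#' @param ys numeric series, n >= 16.
#' @param window "hann" (default), "hamming" or "none".
#' @return list of class `spectrum_psi`: `freqs`, `psi`, `window`,
#'   `n_input`, `n_padded`.
#' @export
spectral_density <- function(ys, window = c("hann", "hamming", "none")) {
  window <- match.arg(window)
  n <- length(ys)
  if (n < 16) stop("need at least 16 points")
  if (anyNA(ys)) stop("missing values")
  x <- ys - mean(ys)
  if (all(x == 0)) warning("constant input: zero spectrum")
  w <- switch(window,
              hann    = 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))),
              hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)),
              none    = rep(1, n))
  x <- x * w
  npad <- as.integer(2^ceiling(log2(n)))
  if (npad > n) x <- c(x, numeric(npad - n))
  F <- stats::fft(x)
  k <- seq_len(npad / 2)
  structure(list(freqs = k / npad, psi = Re(F[k + 1])^2 + Im(F[k + 1])^2,
                 window = window, n_input = n, n_padded = npad),
            class = "spectrum_psi")
}

#' @export
print.spectrum_psi <- function(x, ...) {
  cat(sprintf("Spectral density: %d frequencies (n = %d padded to %d, %s window)\n",
              length(x$freqs), x$n_input, x$n_padded, x$window))
  invisible(x)
}

#' Log-log slope of a spectral density
#'
#' Theil (median-of-pairwise-slopes) regression of log psi on log f over a
#' frequency band. By default the band excludes the top decade of
#' frequencies (f > f_max / 10), which is contaminated by discrete
#' sampling artefacts. A slope near 0 is the white-noise signature; a
#' slope near -2 is the 1/f^2 signature of a Brownian walk.
#'
#' @param spec a `spectrum_psi`.
#' @param fit_band length-2 numeric c(lo, hi) of frequencies to fit over;
#'   NULL for the default band.
#' @return list: `slope`, `ci` (from the Theil rank interval), `n_freqs`.
#' @export
loglog_slope <- function(spec, fit_band = NULL) {
  stopifnot(inherits(spec, "spectrum_psi"))
  if (is.null(fit_band)) fit_band <- c(0, max(spec$freqs) / 10)
  keep <- spec$freqs > fit_band[1] & spec$freqs <= fit_band[2] &
    spec$psi > 0
  if (sum(keep) < 16) stop("fewer than 16 usable frequencies in the band")
  f <- spec$freqs[keep]; p <- spec$psi[keep]
  if (sum(keep) > 1500) {         # cap the O(n^2) pairwise-slope cost
    idx <- unique(round(seq(1, length(f), length.out = 1500)))
    f <- f[idx]; p <- p[idx]
  }
  fit <- theil_regression(log(f), log(p))
  list(slope = fit$beta, ci = fit$beta_ci, n_freqs = length(f))
}

#' Classify a series as white-like or Brownian-like
#'
#' Combines two independent signatures: the log-log spectral slope
#' (white ~ 0, Brownian ~ -2) and the position of the series' Sevcik
#' dimension relative to white and Brownian calibration bands at matched
#' length (judged by the Vysochanskij-Petunin comparison). The label is
#' returned only when the two signatures agree; a dominant spectral peak
#' (peak-to-median power ratio > `peak_ratio`) marks a periodic signal and
#' yields "indeterminate" with a `dominant_peak` annotation.
#'
#' @param ys numeric series, n >= 256.
#' @param white_cal,brown_cal optional precomputed `calibration_ensemble`s
#'   at N = length(ys); generated (M traces, seeded) when NULL.
#' @param M,seed calibration size and seed used when ensembles are
#'   generated internally.
#' @param alpha significance level of the V-P band comparison.
#' @param peak_ratio dominance threshold for the periodicity annotation.
#' @return list of class `series_class`: `label` ("white_like",
#'   "brownian_like" or "indeterminate"), `slope`, `Ds`, `slope_class`,
#'   `dim_class`, `dominant_peak`.
#' @export
classify_series <- function(ys, white_cal = NULL, brown_cal = NULL,
                            M = 20L, seed = 1L, alpha = 0.05,
                            peak_ratio = 100) {
  n <- length(ys)
  if (n < 256) stop("need at least 256 points to classify")
  if (is.null(white_cal)) white_cal <- calibrate("white", n, M, seed)
  if (is.null(brown_cal))
    brown_cal <- calibrate("brownian", n, M, derive_seed(seed, 1))
  stopifnot(white_cal$N == n, brown_cal$N == n)
  spec <- spectral_density(ys)
  sl <- loglog_slope(spec)$slope
  slope_class <- if (sl > -0.75) "white_like" else
    if (sl < -1.25) "brownian_like" else "indeterminate"
  sv <- sevcik_dimension(ys)
  vs_white <- compare_dimensions(sv, white_cal, alpha = alpha)
  vs_brown <- compare_dimensions(sv, brown_cal, alpha = alpha)
  dim_class <- if (!vs_white$significant && vs_brown$significant)
    "white_like"
  else if (vs_white$significant && !vs_brown$significant)
    "brownian_like"
  else "indeterminate"
  peak <- has_dominant_peak(spec, peak_ratio)
  label <- if (peak) "indeterminate"
  else if (slope_class == dim_class) slope_class
  else "indeterminate"
  structure(list(label = label, slope = sl, Ds = sv$Ds,
                 slope_class = slope_class, dim_class = dim_class,
                 dominant_peak = peak),
            class = "series_class")
}

# A peak is "dominant" when it sits away from the lowest bins (where a
# 1/f^2 spectrum legitimately concentrates power) and towers over its
# local background (excluding +-1 leakage bins) by more than peak_ratio.
has_dominant_peak <- function(spec, peak_ratio) {
  k <- which.max(spec$psi)
  if (k <= 3L) return(FALSE)
  nb <- setdiff(max(1L, k - 10L):min(length(spec$psi), k + 10L),
                (k - 1L):(k + 1L))
  bg <- stats::median(spec$psi[nb])
  bg > 0 && spec$psi[k] / bg > peak_ratio
}

#' @export
print.series_class <- function(x, ...) {
  cat(sprintf(
    "Series class: %s (slope %.2f -> %s; Ds %.4f -> %s%s)\n",
    x$label, x$slope, x$slope_class, x$Ds, x$dim_class,
    if (x$dominant_peak) "; dominant spectral peak" else ""))
  invisible(x)
}
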