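#' @keywords internal
new_acf_estimate <- function(lags, values, method, dt) {
  structure(list(lags = as.integer(lags), values = as.numeric(values),
                 method = method, dt = dt),
            class = "acf_estimate")
}

#' @export
print.acf_estimate <- function(x, ...) {
  cat(sprintf("ACF estimate (%s): %d lags, dt = %g\n",
              x$method, length(x$lags), x$dt))
  cat("  rho[0..4] =", format(utils::head(x$values, 5), digits = 4), "\n")
  invisible(x)
}

#' Sample autocorrelation function via the FFT
#'
#' Computes the biased (1/n) linear sample autocovariance through a
#' zero-padded spectral method (padding to at least `2n` avoids circular
#' aliasing, so the result equals the direct time-domain estimator up to
#' floating rounding), then normalizes by the lag-0 value. Lags run 0..n-1.
#'
#' @param x A `time_series` or numeric vector, length at least 4,
#'   non-constant.
#' @return An `acf_estimate` with `method = "fft"` and `values[1] = 1`.
#' @seealso [acf_welch()], [gaussian_acf()], [ess_bartlett()]
#' @export
acf_fft <- function(x) {
  x <- as_time_series(x)
  v <- x$values
  n <- length(v)
  if (n < 4L) stop("ACF estimation needs at least 4 samples", call. = FALSE)
  if (stats::var(v) == 0) stop("zero-variance input: ACF undefined", call. = FALSE)
  v <- v - mean(v)
  m <- stats::nextn(2L * n)
  ps <- Mod(stats::fft(c(v, numeric(m - n))))^2
  ac <- Re(stats::fft(ps, inverse = TRUE))[1:n] / m
  new_acf_estimate(0:(n - 1L), ac / ac[1L], "fft", x$dt)
}

#' Sample autocorrelation via the Welch periodogram
#'
#' Averages Hann-windowed, overlapping-segment periodograms (Welch's method;
#' defaults 256-point windows with 128-point overlap) and inverts the
#' averaged power spectral density to an autocovariance, normalized to 1 at
#' lag 0. The lag support is limited to the window length, which is the
#' mechanism by which Welch-based ESS estimates suppress spurious long-range
#' correlations. Each segment is demeaned before windowing.
#'
#' When the series is shorter than `window_len` the window is reduced to the
#' full series length (with a warning) and the overlap to half of it.
#'
#' @inheritParams acf_fft
#' @param window_len Segment length in samples.
#' @param overlap Overlap between consecutive segments; must be smaller than
#'   `window_len`.
#' @return An `acf_estimate` with `method = "welch"` and lags
#'   `0..window_len-1`.
#' @export
acf_welch <- function(x, window_len = 256L, overlap = 128L) {
  x <- as_time_series(x)
  v <- x$values
  n <- length(v)
  if (overlap >= window_len) {
    stop("'overlap' must be smaller than 'window_len'", call. = FALSE)
  }
  if (n < window_len) {
    warning(sprintf(
      "series length %d < window length %d; using a %d-point window",
      n, window_len, n), call. = FALSE)
    window_len <- n
    overlap <- n %/% 2L
  }
  if (stats::var(v) == 0) stop("zero-variance input: ACF undefined", call. = FALSE)
  v <- v - mean(v)
  L <- as.integer(window_len)
  hop <- L - as.integer(overlap)
  starts <- seq.int(1L, n - L + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / L) # periodic Hann
  psd <- numeric(L)
  for (s in starts) {
    seg <- v[s:(s + L - 1L)]
    seg <- seg - mean(seg)
    psd <- psd + Mod(stats::fft(w * seg))^2
  }
  ac <- Re(stats::fft(psd, inverse = TRUE))[1:L]
  new_acf_estimate(0:(L - 1L), ac / ac[1L], "welch", x$dt)
}

#' Gaussian (Laplace-approximation) autocorrelation model
#'
#' The one-parameter ACF family
#' \eqn{\rho(\tau) = \exp(-\tfrac12 \lambda_2 \tau^2)} obtained from the
#' second-order expansion of any smooth ACF around its mode at lag 0, with
#' curvature parameter \eqn{\lambda_2 = |\rho''(0)|} (the roughness).
#'
#' @param lambda2 Nonnegative roughness, units 1/time^2.
#' @param lags Integer lag sequence (typically `0:L`).
#' @param dt Sampling interval converting lags to time.
#' @return An `acf_estimate` with `method = "gaussian_model"`.
#' @export
gaussian_acf <- function(lambda2, lags, dt = 1) {
  if (!is.numeric(lambda2) || length(lambda2) != 1L || !is.finite(lambda2) ||
      lambda2 < 0) {
    stop("'lambda2' must be a single nonnegative number", call. = FALSE)
  }
  new_acf_estimate(lags, exp(-0.5 * lambda2 * (lags * dt)^2),
                   "gaussian_model", dt)
}
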