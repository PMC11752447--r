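#' @keywords internal
new_roughness_estimate <- function(lambda2, n, method, series_variance, dt) {
  structure(list(lambda2 = lambda2, n = n, method = method,
                 series_variance = series_variance, dt = dt),
            class = "roughness_estimate")
}

#' @export
print.roughness_estimate <- function(x, ...) {
  cat(sprintf("Roughness (second spectral moment), %s method\n", x$method))
  cat(sprintf("  lambda2 = %.6g / time^2   (n = %d, dt = %g)\n",
              x$lambda2, x$n, x$dt))
  invisible(x)
}

#' Roughness from the variance of temporal derivatives
#'
#' Estimates the second spectral moment \eqn{\lambda_2 = |\rho''(0)|} of a
#' standardized wide-sense stationary process from the sample variance of its
#' forward differences. For a unit-variance process with autocorrelation
#' \eqn{\rho}, \eqn{\mathrm{var}(\dot x) = |\rho''(0)|}, so the discrete
#' estimator is
#' \deqn{\hat\lambda_2 = \mathrm{var}(\Delta z) / \Delta t^2,}
#' where \eqn{z} is the series demeaned and scaled to unit sample variance.
#' The roughness is invariant to affine rescaling of the input.
#'
#' At a finite sampling interval the estimator targets
#' \eqn{2(1 - \rho(\Delta t))/\Delta t^2}, which converges to
#' \eqn{|\rho''(0)|} as \eqn{\Delta t \to 0}; for a Gaussian autocorrelation
#' with roughness \eqn{a} the finite-interval expectation is
#' \eqn{2(1 - e^{-a \Delta t^2/2})/\Delta t^2}.
#'
#' @param x A `time_series` or numeric vector (coerced with `dt = 1`),
#'   at least 3 samples, non-constant.
#' @return A `roughness_estimate` with fields `lambda2` (units 1/time^2),
#'   `n`, `method = "derivative"`, `series_variance`, and `dt`.
#' @seealso [roughness_rice()] for the zero-crossing alternative,
#'   [ess_parametric()] for the ESS built from two such estimates.
#' @examples
#' x <- sample_kernel_process(calibrate_kernel("gaussian", 0.01),
#'                            simulation_config(n = 5000, seed = 1))[[1]]
#' roughness_derivative(x)
#' @export
roughness_derivative <- function(x) {
  x <- as_time_series(x)
  v <- x$values
  n <- length(v)
  if (n < 3L) stop("roughness estimation needs at least 3 samples", call. = FALSE)
  s2 <- stats::var(v)
  if (s2 == 0) {
    stop("degenerate input: constant series has undefined roughness", call. = FALSE)
  }
  z <- (v - mean(v)) / sqrt(s2)
  lambda2 <- stats::var(diff(z)) / x$dt^2
  new_roughness_estimate(lambda2, n, "derivative", s2, x$dt)
}

#' Roughness from the zero-crossing rate (Rice's formula)
#'
#' For a zero-mean, unit-variance stationary Gaussian process the expected
#' number of zero crossings per unit time is \eqn{\sqrt{\lambda_2}/\pi}
#' (Rice's formula). Inverting this relation on the observed crossing rate of
#' the demeaned series gives
#' \deqn{\hat\lambda_2 = (\pi\, \hat r_{zc})^2, \qquad
#'       \hat r_{zc} = \frac{\#\{\mathrm{sign\ changes}\}}{(n-1)\,\Delta t}.}
#'
#' A crossing is counted when consecutive demeaned samples have opposite
#' signs; an exact zero inherits the sign of the previous nonzero sample
#' (leading zeros inherit the first nonzero sign). Exact zeros are a
#' measure-zero event for continuous-valued data, so the convention only
#' matters for quantized inputs.
#'
#' @inheritParams roughness_derivative
#' @return A `roughness_estimate` with `method = "rice"`. If the demeaned
#'   series never changes sign a warning is emitted and `lambda2 = 0`.
#' @export
roughness_rice <- function(x) {
  x <- as_time_series(x)
  v <- x$values
  n <- length(v)
  if (n < 3L) stop("roughness estimation needs at least 3 samples", call. = FALSE)
  s2 <- stats::var(v)
  if (s2 == 0) {
    stop("degenerate input: constant series has undefined roughness", call. = FALSE)
  }
  z <- v - mean(v)
  s <- sign(z)
  nz <- s != 0
  # carry the previous nonzero sign over exact zeros (first sign backwards
  # for leading zeros)
  idx <- cumsum(nz)
  signs_nz <- s[nz]
  filled <- signs_nz[pmax(idx, 1L)]
  crossings <- sum(filled[-1L] != filled[-n])
  if (crossings == 0L) {
    warning("no zero crossings in the demeaned series; lambda2 set to 0",
            call. = FALSE)
    return(new_roughness_estimate(0, n, "rice", s2, x$dt))
  }
  r_zc <- crossings / ((n - 1) * x$dt)
  new_roughness_estimate((pi * r_zc)^2, n, "rice", s2, x$dt)
}
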