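#' @keywords internal
new_ess_estimate <- function(nu, n, method) {
  structure(list(nu = nu, n = n, method = method, ess_factor = nu / n),
            class = "ess_estimate")
}

#' @export
print.ess_estimate <- function(x, ...) {
  cat(sprintf("Effective sample size (%s): nu = %.4g of n = %d (factor %.4g)\n",
              x$method, x$nu, x$n, x$ess_factor))
  invisible(x)
}

# clip to [1, n]; nu <= n by construction of the correction, nu >= 1 is the
# logical floor (one fully dependent sample)
clip_nu <- function(nu, n) {
  if (nu < 1 || nu > n) {
    warning(sprintf("ESS estimate %.4g outside [1, n = %d]; clipped", nu, n),
            call. = FALSE)
    nu <- min(max(nu, 1), n)
  }
  nu
}

coerce_roughness <- function(r) {
  if (inherits(r, "roughness_estimate")) return(r)
  if (is.list(r) && !is.null(r$lambda2)) return(r) # already coerced

  if (is.numeric(r) && length(r) == 1L && is.finite(r) && r >= 0) {
    return(list(lambda2 = r, n = NA_integer_, method = "given", dt = 1))
  }
  stop("expected a 'roughness_estimate' or a single nonnegative number",
       call. = FALSE)
}

#' Parametric (Laplace-approximation) effective sample size
#'
#' The closed-form ESS of the correlation between two smooth wide-sense
#' stationary series, obtained by approximating each autocorrelation function
#' with the Gaussian form matched to its curvature at lag 0:
#' \deqn{\nu = n \sqrt{\frac{\lambda_{2,x} + \lambda_{2,y}}{2\pi}},}
#' with roughness measured in per-sample units (\eqn{\lambda_2 \Delta t^2}),
#' so that \eqn{\nu} is dimensionless. With equal roughness \eqn{a} this
#' reduces to \eqn{n\sqrt{a/\pi}}; a pair with heterogeneous roughness is
#' equivalent to a pair sharing their arithmetic-mean roughness.
#'
#' The result is clipped to `[1, n]` (with a warning when clipping occurs).
#'
#' @param rx,ry Roughness of each series: `roughness_estimate` objects or
#'   bare nonnegative numbers (then interpreted in per-sample units). `ry`
#'   defaults to `rx` (equal-roughness case). Not both may be zero.
#' @param n Series length. Defaults to the length recorded in `rx`.
#' @return An `ess_estimate` with `method = "parametric"` (or `"rice"` when
#'   both roughness estimates came from the zero-crossing estimator).
#' @examples
#' ess_parametric(0.01 * pi, n = 1000) # nu = 100
#' @export
ess_parametric <- function(rx, ry = rx, n = NULL) {
  rx <- coerce_roughness(rx)
  ry <- coerce_roughness(ry)
  if (is.null(n)) n <- rx$n
  if (is.na(n) || !is.numeric(n) || n < 2) {
    stop("'n' must be provided and at least 2", call. = FALSE)
  }
  n <- as.integer(n)
  if (!isTRUE(all.equal(rx$dt, ry$dt))) {
    stop("the two roughness estimates use different sampling intervals",
         call. = FALSE)
  }
  lx <- rx$lambda2 * rx$dt^2
  ly <- ry$lambda2 * ry$dt^2
  if (lx == 0 && ly == 0) {
    stop(paste("both roughness estimates are zero: no temporal structure to",
               "correct for (indistinguishable from constant signals)"),
         call. = FALSE)
  }
  nu <- n * sqrt((lx + ly) / (2 * pi))
  method <- if (identical(rx$method, "rice") && identical(ry$method, "rice")) {
    "rice"
  } else {
    "parametric"
  }
  new_ess_estimate(clip_nu(nu, n), n, method)
}

#' Classical ACF-sum (Bartlett-type) effective sample size
#'
#' The reference ESS built from two sample autocorrelation functions:
#' \deqn{\nu = n \Big/ \Big(\rho_0\gamma_0 +
#'   2\sum_{k=1}^{L} \tfrac{n-k}{n}\, \rho_k \gamma_k\Big).}
#' The sum runs over the full shared lag support (`n - 1` for FFT-based
#' ACFs, `window_len - 1` for Welch), which is also the route by which noise
#' accumulates in the denominator for smooth series.
#'
#' @param acf_x,acf_y `acf_estimate` objects (normalized to 1 at lag 0).
#'   Unequal lag supports are truncated to the shorter one.
#' @param n Series length used in the taper and the numerator.
#' @return An `ess_estimate` with method `"bartlett_welch"` if either ACF is
#'   Welch-based, otherwise `"bartlett_fft"`. If the denominator is
#'   non-positive (pathological noise accumulation) `nu` is set to `n` with
#'   a warning.
#' @examples
#' a <- 0.01
#' nu <- ess_bartlett(gaussian_acf(a, 0:9999), gaussian_acf(a, 0:9999), 1e4)
#' nu$nu / (1e4 * sqrt(a / pi)) # close to 1
#' @export
ess_bartlett <- function(acf_x, acf_y, n) {
  if (!inherits(acf_x, "acf_estimate") || !inherits(acf_y, "acf_estimate")) {
    stop("'acf_x' and 'acf_y' must be 'acf_estimate' objects", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2", call. = FALSE)
  L <- min(length(acf_x$values), length(acf_y$values), n) - 1L
  d0 <- acf_x$values[1L] * acf_y$values[1L]
  D <- d0
  if (L >= 1L) {
    k <- seq_len(L)
    D <- d0 + 2 * sum((n - k) / n * acf_x$values[k + 1L] * acf_y$values[k + 1L])
  }
  method <- if (identical(acf_x$method, "welch") ||
                identical(acf_y$method, "welch")) "bartlett_welch" else "bartlett_fft"
  if (D <= 0) {
    warning("non-positive ACF-sum denominator; returning nu = n", call. = FALSE)
    return(new_ess_estimate(as.numeric(n), n, method))
  }
  new_ess_estimate(clip_nu(n / D, n), n, method)
}

#' Asymptotic ESS by quadrature of the ACF product
#'
#' Evaluates \eqn{\nu_\infty = n / \int \rho(\tau)\gamma(\tau)\,d\tau} by
#' adaptive quadrature, with lag measured in samples so that \eqn{\nu} is
#' dimensionless. With the default Gaussian ACF models the integral has the
#' closed form \eqn{\sqrt{2\pi/(a+b)}} and the quadrature reproduces it to
#' near machine precision; supplying `acf_model` evaluates arbitrary
#' integrable ACFs instead.
#'
#' @param lambda2_x,lambda2_y Roughness of the two series (units
#'   1/time^2); used for the Gaussian models when `acf_model` is `NULL`,
#'   and to choose quadrature bounds. `lambda2_y` defaults to `lambda2_x`.
#' @param n Series length.
#' @param acf_model Optional ACF override: a single function `rho(tau)`
#'   (used for both series) or a list of two such functions, with `tau` in
#'   sample units. Integrated over the whole real line.
#' @param dt Sampling interval converting `lambda2` to per-sample units.
#' @return An `ess_estimate` with `method = "integral"`.
#' @examples
#' ess_integral(0.01 * pi, n = 1000)$nu # 100, closed form
#' a <- 0.05 # exp(-a|tau|) model: integral of rho^2 is 1/a, nu = n a
#' ess_integral(n = 1000, acf_model = function(t) exp(-a * abs(t)))$nu
#' @export
ess_integral <- function(lambda2_x = NULL, lambda2_y = lambda2_x, n,
                         acf_model = NULL, dt = 1) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be at least 2", call. = FALSE)
  if (is.null(acf_model)) {
    if (is.null(lambda2_x)) {
      stop("provide 'lambda2_x' (and optionally 'lambda2_y') or 'acf_model'",
           call. = FALSE)
    }
    a <- lambda2_x * dt^2
    b <- lambda2_y * dt^2
    if (a < 0 || b < 0) stop("roughness must be nonnegative", call. = FALSE)
    if (a + b == 0) stop("both roughnesses are zero", call. = FALSE)
    # Gaussian tails are negligible beyond 10 standard widths
    bound <- 10 / sqrt(min(c(a, b)[c(a, b) > 0]))
    f <- function(t) exp(-0.5 * (a + b) * t^2)
    I <- stats::integrate(f, -bound, bound,
                          abs.tol = 1e-12, rel.tol = 1e-10)$value
  } else {
    fns <- if (is.function(acf_model)) list(acf_model, acf_model) else acf_model
    if (!is.list(fns) || length(fns) != 2L || !all(vapply(fns, is.function, TRUE))) {
      stop("'acf_model' must be a function or a list of two functions",
           call. = FALSE)
    }
    f <- function(t) fns[[1L]](t) * fns[[2L]](t)
    I <- tryCatch(
      stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value,
      error = function(e) {
        stop("quadrature of the supplied ACF model failed: ",
             conditionMessage(e), call. = FALSE)
      })
  }
  if (!is.finite(I) || I <= 0) {
    stop("ACF product integral is non-positive or non-finite; the supplied ",
         "model is not a valid autocorrelation", call. = FALSE)
  }
  new_ess_estimate(clip_nu(n / I, n), n, "integral")
}
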