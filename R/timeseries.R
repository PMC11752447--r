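#' Construct a uniformly sampled time series
#'
#' The universal input of the package: an ordered real-valued signal with a
#' constant sampling interval. Most estimators accept plain numeric vectors
#' and coerce them with `dt = 1` (unit sampling), which matches the
#' per-sample convention in which the effective sample size is dimensionless.
#'
#' @param values Numeric vector of at least two finite samples.
#' @param dt Sampling interval in time units; must be a single positive
#'   number. Defaults to 1 (per-sample units).
#' @param name Optional label carried through to printed output.
#'
#' @return An object of class `"time_series"`: a list with elements
#'   `values`, `dt`, and `name`.
#'
#' @examples
#' x <- time_series(sin(seq(0, 10, by = 0.1)), dt = 0.1, name = "demo")
#' x
#' @export
time_series <- function(values, dt = 1, name = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a time series needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("time series values must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, dt = dt, name = name),
            class = "time_series")
}

#' Coerce to a time series
#'
#' @param x A `time_series` object or a numeric vector.
#' @param dt Sampling interval used when `x` is a bare vector.
#' @return A `time_series` object.
#' @export
as_time_series <- function(x, dt = 1) {
  if (inherits(x, "time_series")) return(x)
  time_series(x, dt = dt)
}

#' @export
print.time_series <- function(x, ...) {
  nm <- if (is.null(x$name)) "" else sprintf(" '%s'", x$name)
  cat(sprintf("Time series%s: %d samples, dt = %g\n", nm,
              length(x$values), x$dt))
  cat("  head:", format(utils::head(x$values, 5), digits = 4), "\n")
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)
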