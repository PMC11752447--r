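#' Significance quantile for a correlation under the corrected null
#'
#' The smallest correlation magnitude rejected at the two-sided 5% level,
#' obtained by inverting the Fisher transform of the 97.5% normal quantile:
#' \deqn{Q_{97.5\%} = \tanh\!\big(z_{0.975}/\sqrt{\nu - 3}\big).}
#' Strictly decreasing in `nu` (more effective samples allow rejecting at
#' smaller correlations) with limit 0 as `nu` grows.
#'
#' The default `"nu_minus_3"` convention uses \eqn{\sqrt{\nu-3}} so the
#' quantile inverts the corrected test exactly
#' (`abs(r) > q975(nu)` if and only if `p < 0.05`); the `"nu"` convention
#' uses \eqn{\sqrt{\nu}} instead.
#'
#' @param nu Effective sample size(s); vectorized. Must exceed 3 under the
#'   default convention (0 under `"nu"`).
#' @param quantile_convention `"nu_minus_3"` (default) or `"nu"`.
#' @return Numeric vector of rejection thresholds in (0, 1).
#' @examples
#' q975(103) # about 0.1935
#' @export
q975 <- function(nu, quantile_convention = c("nu_minus_3", "nu")) {
  quantile_convention <- match.arg(quantile_convention)
  df <- if (quantile_convention == "nu_minus_3") nu - 3 else nu
  if (any(df <= 0)) {
    stop("insufficient effective sample size: the corrected test needs nu > 3",
         call. = FALSE)
  }
  tanh(stats::qnorm(0.975) / sqrt(df))
}

#' Corrected Fisher-z significance of a correlation coefficient
#'
#' The null distribution of a correlation between two series with effective
#' sample size \eqn{\nu} is
#' \eqn{\sqrt{\nu - 3}\,\mathrm{arctanh}(r) \sim N(0, 1)}. This helper
#' evaluates the test for a given `(r, nu)` pair; [corr_test()] wraps it with
#' ESS estimation from data.
#'
#' @param r Correlation coefficient in \[-1, 1\].
#' @param nu Effective sample size, must exceed 3 (need not be an integer).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @param quantile_convention Passed to [q975()].
#' @return A list with `r`, `z = arctanh(r)`, `nu`,
#'   `statistic = z * sqrt(nu - 3)`, `p.value`, and `q975`. For `|r| = 1`
#'   the statistic is infinite and `p.value = 0`, with a warning.
#' @examples
#' corr_significance(0.3, 103) # statistic about 3.095, p about 0.00197
#' @export
corr_significance <- function(r, nu,
                              alternative = c("two.sided", "greater", "less"),
                              quantile_convention = c("nu_minus_3", "nu")) {
  alternative <- match.arg(alternative)
  quantile_convention <- match.arg(quantile_convention)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) > 1) {
    stop("'r' must be a single correlation in [-1, 1]", call. = FALSE)
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 3) {
    stop("insufficient effective sample size: the corrected test needs nu > 3",
         call. = FALSE)
  }
  if (abs(r) == 1) {
    warning("|r| = 1: Fisher statistic is infinite, p-value reported as 0",
            call. = FALSE)
  }
  z <- atanh(r)
  statistic <- z * sqrt(nu - 3)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(statistic)),
              greater   = stats::pnorm(statistic, lower.tail = FALSE),
              less      = stats::pnorm(statistic))
  list(r = r, z = z, nu = nu, statistic = statistic, p.value = p,
       q975 = q975(nu, quantile_convention))
}

# effective sample size of a pair of series under the chosen estimator
pair_ess <- function(x, y, ess_method) {
  n <- length(x$values)
  switch(ess_method,
    parametric = ess_parametric(roughness_derivative(x),
                                roughness_derivative(y), n),
    rice       = ess_parametric(roughness_rice(x), roughness_rice(y), n),
    fft        = ess_bartlett(acf_fft(x), acf_fft(y), n),
    welch      = ess_bartlett(acf_welch(x), acf_welch(y), n),
    integral   = ess_integral(roughness_derivative(x)$lambda2,
                              roughness_derivative(y)$lambda2, n,
                              dt = x$dt))
}

#' Test the correlation between two autocorrelated time series
#'
#' Computes a Pearson (or Spearman) correlation between two equally long,
#' uniformly sampled series and assesses its significance with the
#' ESS-corrected Fisher-z test: the effective sample size \eqn{\nu} replaces
#' the raw length \eqn{n} in the null
#' \eqn{\sqrt{\nu-3}\,\mathrm{arctanh}(r) \sim N(0,1)}, compensating for the
#' degrees of freedom lost to temporal autocorrelation.
#'
#' ESS estimators: `"parametric"` (derivative-variance roughness in the
#' Laplace closed form; the default, O(n)), `"rice"` (zero-crossing
#' roughness in the same closed form), `"fft"` / `"welch"` (classical
#' ACF-sum references), `"integral"` (quadrature of the fitted Gaussian ACF
#' product). For the Spearman variant both series are rank-transformed first
#' and the same ESS machinery is applied to the rank series, which preserve
#' the temporal dependence structure.
#'
#' @param x,y `time_series` objects or numeric vectors of equal length and
#'   sampling interval.
#' @param ess_method One of `"parametric"`, `"fft"`, `"welch"`, `"rice"`,
#'   `"integral"`.
#' @param coefficient_kind `"pearson"` (default) or `"spearman"`.
#' @param alternative,quantile_convention Passed to [corr_significance()].
#' @param dt Sampling interval used when `x`/`y` are bare vectors.
#' @return An object of class `"corr_test"`: a list with `r`,
#'   `coefficient_kind`, `z`, `nu`, `ess_factor`, `statistic`, `p.value`,
#'   `alternative`, `q975`, `method` (ESS method tag), and `n`.
#' @examples
#' cfg <- simulation_config(n = 2000, n_paths = 2, seed = 7)
#' p <- sample_kernel_process(calibrate_kernel("gaussian", 0.01), cfg)
#' corr_test(p[[1]], p[[2]])
#' @export
corr_test <- function(x, y,
                      ess_method = c("parametric", "fft", "welch", "rice",
                                     "integral"),
                      coefficient_kind = c("pearson", "spearman"),
                      alternative = c("two.sided", "greater", "less"),
                      quantile_convention = c("nu_minus_3", "nu"),
                      dt = 1) {
  ess_method <- match.arg(ess_method)
  coefficient_kind <- match.arg(coefficient_kind)
  x <- as_time_series(x, dt)
  y <- as_time_series(y, dt)
  if (length(x$values) != length(y$values)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  if (!isTRUE(all.equal(x$dt, y$dt))) {
    stop("'x' and 'y' must share the same sampling interval", call. = FALSE)
  }
  if (coefficient_kind == "spearman") {
    x <- time_series(rank(x$values, ties.method = "average"), x$dt, x$name)
    y <- time_series(rank(y$values, ties.method = "average"), y$dt, y$name)
  }
  r <- stats::cor(x$values, y$values)
  ess <- pair_ess(x, y, ess_method)
  sig <- corr_significance(r, ess$nu, alternative = alternative,
                           quantile_convention = quantile_convention)
  structure(list(r = r, coefficient_kind = coefficient_kind, z = sig$z,
                 nu = ess$nu, ess_factor = ess$ess_factor,
                 statistic = sig$statistic, p.value = sig$p.value,
                 alternative = match.arg(alternative), q975 = sig$q975,
                 method = ess$method, n = ess$n),
            class = "corr_test")
}

#' @export
print.corr_test <- function(x, ...) {
  cat("\n\tESS-corrected correlation test\n\n")
  cat(sprintf("%s r = %.4f, n = %d, ESS nu = %.2f (factor %.4f, %s)\n",
              x$coefficient_kind, x$r, x$n, x$nu, x$ess_factor, x$method))
  cat(sprintf("Fisher z = %.4f, statistic = %.4f, %s p-value = %.4g\n",
              x$z, x$statistic, x$alternative, x$p.value))
  cat(sprintf("97.5%% rejection threshold |r| > %.4f\n\n", x$q975))
  invisible(x)
}

series_list_from <- function(x, dt) {
  if (inherits(x, "series_table")) return(x$series)
  if (is.data.frame(x) || is.matrix(x)) {
    labels <- colnames(x)
    if (is.null(labels)) labels <- paste0("V", seq_len(ncol(x)))
    x <- as.data.frame(x)
    out <- lapply(seq_along(x), function(j) {
      time_series(x[[j]], dt = dt, name = labels[j])
    })
    names(out) <- labels
    return(out)
  }
  if (is.list(x)) {
    out <- lapply(x, as_time_series, dt = dt)
    if (is.null(names(out)) || any(names(out) == "")) {
      names(out) <- paste0("V", seq_along(out))
    }
    return(out)
  }
  stop("expected a series_table, matrix, data.frame, or list of series",
       call. = FALSE)
}

#' Pairwise connectivity matrices with ESS-corrected significance
#'
#' Applies [corr_test()] to every pair of channels and assembles symmetric
#' matrices of correlations, effective sample sizes, p-values, rejection
#' thresholds, and significance flags — the all-pairs analysis used for
#' power-based functional connectivity. Off-diagonal p-values may optionally
#' be Benjamini-Hochberg adjusted before thresholding.
#'
#' Degenerate channels (for example constant signals) are reported as `NA`
#' rows/columns with a warning rather than failing the whole analysis.
#'
#' @param x Multi-channel input: a `series_table` from
#'   [read_series_csv()], a numeric matrix or data frame (columns =
#'   channels), or a list of `time_series` of equal length.
#' @param ess_method,coefficient_kind,quantile_convention As in
#'   [corr_test()].
#' @param mt_correction `"none"` (default) or `"bh"`
#'   (Benjamini-Hochberg across the off-diagonal p-values).
#' @param alpha Significance level for the `significant` matrix.
#' @param dt Sampling interval when `x` carries none.
#' @return An object of class `"connectivity_result"`: matrices `r` (unit
#'   diagonal), `nu`, `p`, `q975`, logical `significant`, plus `method`,
#'   `mt_correction`, and `alpha`.
#' @export
pairwise_connectivity <- function(x,
                                  ess_method = c("parametric", "fft", "welch",
                                                 "rice", "integral"),
                                  mt_correction = c("none", "bh"),
                                  coefficient_kind = c("pearson", "spearman"),
                                  quantile_convention = c("nu_minus_3", "nu"),
                                  alpha = 0.05, dt = 1) {
  ess_method <- match.arg(ess_method)
  mt_correction <- match.arg(mt_correction)
  coefficient_kind <- match.arg(coefficient_kind)
  quantile_convention <- match.arg(quantile_convention)
  series <- series_list_from(x, dt)
  m <- length(series)
  if (m < 2L) stop("connectivity needs at least 2 series", call. = FALSE)
  lens <- vapply(series, function(s) length(s$values), 0L)
  if (length(unique(lens)) != 1L) {
    stop("all series must have equal length", call. = FALSE)
  }
  labels <- names(series)
  if (coefficient_kind == "spearman") {
    series <- lapply(series, function(s) {
      time_series(rank(s$values, ties.method = "average"), s$dt, s$name)
    })
  }
  n <- lens[1L]
  ok <- rep(TRUE, m)
  state <- vector("list", m)
  for (j in seq_len(m)) {
    state[[j]] <- tryCatch(
      switch(ess_method,
             parametric = roughness_derivative(series[[j]]),
             integral   = roughness_derivative(series[[j]]),
             rice       = roughness_rice(series[[j]]),
             fft        = acf_fft(series[[j]]),
             welch      = acf_welch(series[[j]])),
      error = function(e) NULL)
    if (is.null(state[[j]])) ok[j] <- FALSE
  }
  if (any(!ok)) {
    warning("degenerate series reported as NA: ",
            paste(labels[!ok], collapse = ", "), call. = FALSE)
  }
  mk <- function(diagval) {
    out <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
    diag(out) <- diagval
    out
  }
  R <- mk(1); NU <- mk(NA_real_); P <- mk(NA_real_); Q <- mk(NA_real_)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (!ok[i] || !ok[j]) next
      r <- stats::cor(series[[i]]$values, series[[j]]$values)
      ess <- switch(ess_method,
        parametric = ess_parametric(state[[i]], state[[j]], n),
        rice       = ess_parametric(state[[i]], state[[j]], n),
        integral   = ess_integral(state[[i]]$lambda2, state[[j]]$lambda2, n,
                                  dt = series[[i]]$dt),
        ess_bartlett(state[[i]], state[[j]], n))
      sig <- withCallingHandlers(
        corr_significance(r, ess$nu, quantile_convention = quantile_convention),
        warning = function(w) invokeRestart("muffleWarning"))
      R[i, j] <- R[j, i] <- r
      NU[i, j] <- NU[j, i] <- ess$nu
      P[i, j] <- P[j, i] <- sig$p.value
      Q[i, j] <- Q[j, i] <- sig$q975
    }
  }
  Padj <- P
  if (mt_correction == "bh") {
    up <- upper.tri(P)
    Padj[up] <- stats::p.adjust(P[up], method = "BH")
    Padj[lower.tri(Padj)] <- t(Padj)[lower.tri(Padj)]
  }
  SIG <- Padj < alpha
  diag(SIG) <- NA
  structure(list(r = R, nu = NU, p = Padj, q975 = Q, significant = SIG,
                 method = ess_method, mt_correction = mt_correction,
                 alpha = alpha),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  m <- nrow(x$r)
  nsig <- sum(x$significant[upper.tri(x$significant)], na.rm = TRUE)
  cat(sprintf(
    "Connectivity (%s ESS, %s correction): %d channels, %d/%d significant pairs at alpha = %g\n",
    x$method, x$mt_correction, m, nsig, m * (m - 1) / 2, x$alpha))
  invisible(x)
}
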