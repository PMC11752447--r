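# Independent oracles and fixture builders used across the suite.

# Direct O(n^2)-style time-domain biased sample ACF (the brute-force
# reference for the spectral implementation).
acf_direct <- function(v) {
  v <- v - mean(v)
  n <- length(v)
  ac <- vapply(0:(n - 1L), function(k) {
    sum(v[1:(n - k)] * v[(1 + k):n]) / n
  }, 0)
  ac / ac[1L]
}

# Gaussian-ACF process paths at a given roughness (the canonical null model).
gpga_paths <- function(a, n, n_paths = 1L, seed = 1L, dt = 1) {
  sample_kernel_process(
    calibrate_kernel("gaussian", a, dt = dt),
    simulation_config(n = n, n_paths = n_paths, target_roughness = a,
                      seed = seed, dt = dt))
}

# hand-built ACF estimate, for feeding ess_bartlett synthetic shapes
fake_acf <- function(values, method = "fft", dt = 1) {
  structure(list(lags = seq_along(values) - 1L, values = values,
                 method = method, dt = dt),
            class = "acf_estimate")
}

expected_gaussian_diff_roughness <- function(a, dt = 1) {
  2 * (1 - exp(-a * dt^2 / 2)) / dt^2
}
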