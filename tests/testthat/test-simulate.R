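test_that("sampling is deterministic and respects the per-path seed policy", {
  spec <- calibrate_kernel("gaussian", 1e-2)
  cfg <- simulation_config(n = 1000, n_paths = 3, seed = 99)
  a <- sample_kernel_process(spec, cfg)
  b <- sample_kernel_process(spec, cfg)
  for (i in 1:3) expect_identical(a[[i]]$values, b[[i]]$values)
  # path 1 is reproducible independently of how many paths are drawn
  solo <- sample_kernel_process(spec,
                                simulation_config(n = 1000, seed = 99))
  expect_identical(solo[[1]]$values, a[[1]]$values)
  # nearby master seeds give unrelated streams
  shifted <- sample_kernel_process(
    spec, simulation_config(n = 1000, n_paths = 3, seed = 100))
  expect_false(identical(shifted[[1]]$values, a[[2]]$values))
})

test_that("sampled paths are standardized, stationary draws", {
  # roughness 1e-2 keeps the variance-of-variance of each third small
  # enough (about 1/sqrt(n*sqrt(a/pi)/3)) for the check to have power
  for (fam in c("gaussian", "laplace", "sinc")) {
    spec <- calibrate_kernel(fam, 1e-2)
    x <- sample_kernel_process(
      spec, simulation_config(n = 30000, seed = 400))[[1]]$values
    n <- length(x)
    expect_lt(abs(mean(x)), 3 / sqrt(n * 1e-2)) # ~n*sqrt(a) effective samples
    expect_gt(stats::var(x), 0.9)
    expect_lt(stats::var(x), 1.1)
    thirds <- split(x, rep(1:3, each = n / 3))
    vv <- vapply(thirds, stats::var, 0)
    expect_lt(max(vv) / min(vv), 1.25)
  }
})

test_that("gaussian kernel calibration yields the analytic ACF and roughness", {
  a <- 1e-2
  spec <- calibrate_kernel("gaussian", a)
  expect_equal(spec$width_param, 1 / sqrt(2 * a), tolerance = 1e-12)
  x <- sample_kernel_process(spec, simulation_config(n = 1e5, seed = 8))[[1]]
  est <- roughness_derivative(x)$lambda2
  expect_gt(est, 0.0095)
  expect_lt(est, 0.0105)
  # sample lag-1 autocorrelation close to the theoretical exp(-a/2)
  r1 <- acf_fft(x)$values[2]
  expect_equal(r1, exp(-a / 2), tolerance = 1e-3)
})

test_that("laplace and sinc calibration hit the target within 2 percent", {
  for (fam in c("laplace", "sinc")) {
    spec <- calibrate_kernel(fam, 1e-3)
    expect_equal(expected_roughness(spec), 1e-3, tolerance = 1e-6)
    paths <- sample_kernel_process(
      spec, simulation_config(n = 1e5, n_paths = 50, seed = 500))
    est <- vapply(paths, function(p) roughness_derivative(p)$lambda2, 0)
    expect_lt(abs(mean(est) / 1e-3 - 1), 0.02)
  }
})

test_that("calibration rejects impossible requests", {
  expect_error(calibrate_kernel("gaussian", 0), "positive")
  expect_error(calibrate_kernel("sinc", -1), "positive")
  expect_error(calibrate_kernel("sinc", 1e-12), "infeasibly wide")
  expect_error(kernel_spec("sinc", width_param = 4), "Nyquist")
})

test_that("laplace-kernel ACF decays much slower than its Gaussian fit", {
  a <- 1e-3
  spec <- calibrate_kernel("laplace", a)
  paths <- sample_kernel_process(
    spec, simulation_config(n = 2000, n_paths = 20, seed = 600))
  avg <- rowMeans(vapply(paths, function(p) acf_fft(p)$values,
                         numeric(2000)))
  lag <- round(3 / sqrt(a))
  gauss_fit <- exp(-0.5 * a * lag^2)
  expect_gt(avg[lag + 1L] / gauss_fit, 2)
})

test_that("independent paths are uncorrelated on average", {
  paths <- sample_kernel_process(
    calibrate_kernel("gaussian", 1e-2),
    simulation_config(n = 2000, n_paths = 40, seed = 700))
  rs <- vapply(1:20, function(i) {
    stats::cor(paths[[2 * i - 1]]$values, paths[[2 * i]]$values)
  }, 0)
  expect_lt(abs(mean(rs)), 0.06)   # centred at zero
  expect_lt(mean(abs(rs)), 0.15)   # scale set by the corrected null
})
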