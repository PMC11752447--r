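test_that("parametric ESS matches the closed form and its reductions", {
  expect_equal(ess_parametric(0.01 * pi, n = 1000)$nu, 100, tolerance = 1e-12)
  expect_equal(ess_parametric(1e-3, 4e-3, n = 2000)$nu,
               2000 * sqrt(5e-3 / (2 * pi)), tolerance = 1e-12)
  expect_equal(ess_parametric(1e-3, 4e-3, n = 2000)$nu, 56.41896,
               tolerance = 1e-6)
  expect_error(ess_parametric(0, 0, n = 100), "zero")

  # equal-roughness reduction to n*sqrt(a/pi), exactly
  for (a in c(1e-4, 1e-2, 0.5)) {
    expect_equal(ess_parametric(a, a, n = 5000)$nu, 5000 * sqrt(a / pi),
                 tolerance = 1e-15)
  }
  # heterogeneous pair equals a homogeneous pair at the mean roughness
  set.seed(3)
  for (i in 1:10) {
    ab <- stats::runif(2, 1e-4, 0.2)
    m <- mean(ab)
    expect_equal(ess_parametric(ab[1], ab[2], n = 3000)$nu,
                 ess_parametric(m, m, n = 3000)$nu, tolerance = 1e-12)
  }
})

test_that("parametric ESS is monotone in roughness and linear in n", {
  grid <- c(1e-4, 1e-3, 1e-2, 1e-1)
  nus <- vapply(grid, function(a) ess_parametric(a, 1e-3, n = 1e5)$nu, 0)
  expect_true(all(diff(nus) > 0))
  expect_equal(ess_parametric(1e-2, 1e-2, n = 2000)$nu,
               2 * ess_parametric(1e-2, 1e-2, n = 1000)$nu,
               tolerance = 1e-12)
})

test_that("ESS estimates are clipped to [1, n] with a warning", {
  expect_warning(hi <- ess_parametric(2 * pi, 2 * pi, n = 100), "clipped")
  expect_identical(hi$nu, 100)
  expect_warning(lo <- ess_parametric(1e-9, 1e-9, n = 100), "clipped")
  expect_identical(lo$nu, 1)
  expect_true(lo$ess_factor > 0 && hi$ess_factor <= 1)
})

test_that("ACF-sum ESS reproduces the degenerate identities exactly", {
  n <- 500L
  white <- fake_acf(c(1, numeric(n - 1L)))
  expect_identical(ess_bartlett(white, white, n)$nu, 500)
  ones <- fake_acf(rep(1, n))
  expect_equal(ess_bartlett(ones, ones, n)$nu, 1, tolerance = 1e-12)
  # opposite-signed ACFs can drive the denominator negative
  an <- fake_acf(c(1, rep(0.9, n - 1L)))
  bn <- fake_acf(c(1, rep(-0.9, n - 1L)))
  expect_warning(res <- ess_bartlett(an, bn, n), "non-positive")
  expect_identical(res$nu, 500)
})

test_that("ACF-sum ESS on exact Gaussian ACFs matches the parametric closed form", {
  n <- 1e4L
  for (a in c(1e-3, 1e-2, 1e-1)) {
    g <- gaussian_acf(a, 0:(n - 1L))
    nu <- ess_bartlett(g, g, n)$nu
    expect_lt(abs(nu / (n * sqrt(a / pi)) - 1), 0.02)
  }
  # provenance tagging follows the ACF method
  set.seed(9)
  v <- gpga_paths(1e-2, 2000, seed = 9)[[1]]
  expect_identical(ess_bartlett(acf_welch(v), acf_fft(v), 2000)$method,
                   "bartlett_welch")
  expect_identical(ess_bartlett(acf_fft(v), acf_fft(v), 2000)$method,
                   "bartlett_fft")
})

test_that("quadrature ESS agrees with closed forms and is symmetric", {
  expect_equal(ess_integral(0.01 * pi, n = 1000)$nu, 100, tolerance = 1e-6)
  grid <- c(1e-4, 1e-3, 1e-2, 1e-1, 1)
  for (a in grid) {
    for (b in grid) {
      nu <- ess_integral(a, b, n = 1e4)$nu
      expect_lt(abs(nu / (1e4 * sqrt((a + b) / (2 * pi))) - 1), 1e-8)
      expect_equal(nu, ess_integral(b, a, n = 1e4)$nu, tolerance = 1e-12)
    }
  }
  # exponential-ACF model: integral of exp(-2a|t|) is 1/a, nu = n a
  a <- 0.05
  expect_equal(ess_integral(n = 1000,
                            acf_model = function(t) exp(-a * abs(t)))$nu,
               1000 * a, tolerance = 1e-8)
  expect_error(ess_integral(n = 1000, acf_model = function(t) -abs(t)),
               "not a valid autocorrelation|failed")
})
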