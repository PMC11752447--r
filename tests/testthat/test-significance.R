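test_that("corrected Fisher test matches high-precision reference values", {
  s <- corr_significance(0.3, 103)
  expect_equal(s$statistic, atanh(0.3) * 10, tolerance = 1e-12)
  expect_equal(s$statistic, 3.0952, tolerance = 1e-4)
  expect_equal(s$p.value, 2 * stats::pnorm(-atanh(0.3) * 10),
               tolerance = 1e-12)
  expect_equal(s$p.value, 0.00197, tolerance = 2e-3)

  z <- corr_significance(0, 50)
  expect_identical(z$statistic, 0)
  expect_identical(z$p.value, 1)

  expect_error(corr_significance(0.5, 3), "nu > 3")
  expect_warning(perfect <- corr_significance(1, 100), "infinite")
  expect_identical(perfect$p.value, 0)
})

test_that("Fisher transform round-trips and the quantile inverts the test", {
  set.seed(2)
  r <- c(stats::runif(50, -0.999999, 0.999999), 0.999999, -0.999999)
  expect_equal(tanh(atanh(r)), r, tolerance = 1e-12)

  # |r| > q975(nu) if and only if p < 0.05
  for (nu in c(10, 40, 200)) {
    thr <- q975(nu)
    for (r in c(0.999 * thr, 1.001 * thr, 0.5 * thr, min(2 * thr, 0.99))) {
      p <- corr_significance(r, nu)$p.value
      expect_identical(p < 0.05, abs(r) > thr)
    }
  }
})

test_that("q975 matches the closed form and decreases with the ESS", {
  expect_equal(q975(103), tanh(stats::qnorm(0.975) / 10), tolerance = 1e-12)
  expect_equal(q975(103), 0.1935, tolerance = 2e-4)
  expect_lt(q975(1e9), 1e-4)
  q <- q975(c(10, 100, 1000))
  expect_true(all(diff(q) < 0))
  expect_error(q975(3), "nu > 3")
  # literal convention uses nu instead of nu - 3
  expect_equal(q975(103, "nu"), tanh(stats::qnorm(0.975) / sqrt(103)),
               tolerance = 1e-12)
})

test_that("corr_test handles degenerate and orthogonal inputs per contract", {
  x <- gpga_paths(1e-2, 1000, seed = 12)[[1]]
  expect_warning(same <- corr_test(x, x), "infinite")
  expect_identical(same$r, 1)
  expect_identical(same$p.value, 0)

  # sine and cosine over full periods are exactly orthogonal
  t <- seq_len(1000)
  ct <- corr_test(sin(2 * pi * t / 20), cos(2 * pi * t / 20))
  expect_equal(ct$r, 0, tolerance = 1e-12)
  expect_equal(ct$p.value, 1, tolerance = 1e-10)

  expect_error(corr_test(rnorm(100), rnorm(99)), "equal length")
})

test_that("Spearman variant ranks first and reuses the ESS machinery", {
  set.seed(14)
  p <- gpga_paths(1e-2, 2000, n_paths = 2, seed = 14)
  x <- p[[1]]$values
  y <- p[[2]]$values
  ct <- corr_test(x, y, coefficient_kind = "spearman")
  expect_equal(ct$r, stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  # invariant under monotone marginal transforms of the inputs
  ct2 <- corr_test(exp(x), y, coefficient_kind = "spearman")
  expect_equal(ct2$r, ct$r, tolerance = 1e-12)
  expect_equal(ct2$nu, ct$nu, tolerance = 1e-12)
})

test_that("parametric ESS on sampled white noise is mildly conservative", {
  # white noise violates the smoothness assumption; the derivative roughness
  # is exactly 2 per sample, so nu -> n*sqrt(2/pi) (about 0.80 n) and the
  # corrected test is slightly conservative rather than anticonservative
  set.seed(15)
  nus <- replicate(20, corr_test(rnorm(2000), rnorm(2000))$nu)
  expect_equal(mean(nus) / 2000, sqrt(2 / pi), tolerance = 0.02)
  pv <- replicate(200, corr_test(rnorm(500), rnorm(500))$p.value)
  expect_lte(mean(pv < 0.05), 0.06)
})

test_that("pairwise connectivity assembles symmetric, coherent matrices", {
  paths <- gpga_paths(1e-2, 2000, n_paths = 3, seed = 16)
  res <- pairwise_connectivity(paths)
  for (mat in c("r", "nu", "p", "q975")) {
    expect_identical(dim(res[[mat]]), c(3L, 3L))
    expect_equal(res[[mat]], t(res[[mat]]), tolerance = 1e-15)
  }
  expect_identical(unname(diag(res$r)), rep(1, 3))
  offp <- res$p[upper.tri(res$p)]
  expect_true(all(offp > 0 & offp <= 1))
  expect_identical(res$significant[upper.tri(res$significant)],
                   offp < 0.05)

  # a duplicated channel is trivially significant
  dup <- pairwise_connectivity(list(a = paths[[1]], b = paths[[1]],
                                    c = paths[[2]]))
  expect_true(dup$significant["a", "b"])
  expect_identical(dup$r["a", "b"], 1)
})

test_that("connectivity reports degenerate channels as NA, not failure", {
  paths <- gpga_paths(1e-2, 500, n_paths = 2, seed = 17)
  bad <- list(x = paths[[1]], flat = time_series(rep(1, 500)),
              y = paths[[2]])
  expect_warning(res <- pairwise_connectivity(bad), "flat")
  expect_true(all(is.na(res$p["flat", ])))
  expect_false(anyNA(res$p["x", "y"]))
})

test_that("Benjamini-Hochberg correction keeps the all-null discovery fraction near alpha", {
  fracs <- vapply(1:5, function(s) {
    paths <- gpga_paths(1e-2, 1000, n_paths = 6, seed = 300 + s)
    res <- pairwise_connectivity(paths, mt_correction = "bh")
    mean(res$significant[upper.tri(res$significant)])
  }, 0)
  expect_lte(mean(fracs), 0.06)
})
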