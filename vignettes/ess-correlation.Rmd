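---
title: "Effective sample size and correlation significance for smooth time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective sample size and correlation significance for smooth time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsess)
```

## The problem and the model

Pearson's (or Spearman's) correlation between two time series is routinely
tested with the Fisher transform: under independence of the `n` sample
pairs, `sqrt(n - 3) * arctanh(r)` is approximately standard normal. Real
physiological signals — wavelet band power of EEG, limb trajectories,
haemodynamic signals — are temporally autocorrelated, so their `n` samples
carry fewer than `n` degrees of freedom and the classical test is
overconfident, often by many orders of magnitude in the p-value.

The standard correction replaces `n` by an effective sample size (ESS)
`nu`: the number of *independent* samples that would produce comparable
test statistics. For wide-sense stationary series with autocorrelation
functions (ACFs) `rho` and `gamma`, the classical ACF-sum estimator is

    nu = n / ( rho_0 gamma_0 + 2 sum_{k=1}^{n-1} ((n-k)/n) rho_k gamma_k ).

As `n` grows and the sampling interval shrinks, the denominator converges
to the integral of the ACF product, giving the asymptotic form
`nu = n / integral( rho(tau) gamma(tau) dtau )` (lag measured in samples).

This package's central estimator evaluates that integral by a **Laplace
approximation**: any smooth ACF with its mode at lag 0 is locally
`rho(tau) ≈ exp(-0.5 * lambda2 * tau^2)`, where `lambda2 = |rho''(0)|` is
the **second spectral moment**, or roughness, of the process. For two
Gaussian-form ACFs the integral is `sqrt(2*pi/(lambda2_x + lambda2_y))`,
so

    nu = n * sqrt( (lambda2_x + lambda2_y) / (2*pi) ).

Two properties make this practical. First, for a unit-variance process the
roughness equals the variance of its temporal derivative, estimated in
O(n) from forward differences of the standardized series
(`roughness_derivative()`); a zero-crossing alternative via Rice's formula
is provided (`roughness_rice()`). Second, a pair with unequal roughness is
exactly equivalent to a pair sharing the arithmetic-mean roughness, so the
homogeneous case is fully general. With equal roughness `a` the formula
reduces to `n * sqrt(a/pi)`.

The extracted rendering of the closed form is ambiguous about the radical;
we adopt the square-root form because it is forced by substituting the
Gaussian product integral into the asymptotic expression, and because the
equal-roughness reduction to `n*sqrt(a/pi)` is only consistent with it.

## Assumptions

* Both series are (approximately) wide-sense stationary and *smooth*:
  their ACF is twice differentiable at the mode. No detrending beyond
  demeaning is applied — trend-contaminated or nonstationary signals are
  out of scope.
* The correction targets the *null* distribution of `r`; the test is a
  significance test, not a confidence interval for `r`.
* The Fisher null needs `nu > 3`; estimators returning `nu <= 3` raise an
  error rather than producing an undefined statistic.

## Estimators and tunable parameters

`corr_test(x, y, ess_method = ...)` supports:

* `parametric` (default) — derivative-variance roughness in the closed
  form. O(n), no tuning parameters.
* `rice` — zero-crossing roughness in the same closed form. A crossing is
  a sign change of the demeaned series; exact zeros inherit the previous
  nonzero sign (a measure-zero convention for continuous data).
* `fft` — ACF-sum estimator with the full-support biased sample ACF
  (zero-padded spectral computation, identical to the direct time-domain
  estimator to 1e-10). The full lag sum is deliberate: it is the classical
  reference, including its noise accumulation.
* `welch` — ACF-sum estimator from the Welch periodogram: Hann windows of
  256 points with 128-point overlap by default (the conventional setting),
  each segment demeaned; the lag support is capped at the window length.
  Series shorter than the window reduce it with a warning.
* `integral` — adaptive quadrature of the fitted Gaussian ACF product,
  over ±10 standard widths with absolute tolerance 1e-12 (Gaussian tails
  beyond that range are < 1e-21 of the mass). Mostly useful for supplying
  analytic ACF models via `acf_model =`.

Estimates are clipped to `[1, n]` with a warning; `nu` is used as a
continuous quantity (no rounding). Roughness is reported in `1/time^2`
using the user's `dt`, and the ESS formula consumes per-sample roughness
`lambda2 * dt^2`, so `nu` is dimensionless and `dt` cancels.

Significance quantiles use `q975(nu) = tanh(qnorm(0.975)/sqrt(nu - 3))`,
so `|r| > q975(nu)` holds exactly when the two-sided p-value is below
0.05. A literal-reading switch `quantile_convention = "nu"` replaces
`nu - 3` by `nu`; the difference is negligible for `nu` above ~30. The
Spearman variant rank-transforms both series first and runs the identical
ESS machinery on the rank series, which preserve the temporal dependence
structure; it is the appropriate choice for markedly non-Gaussian margins.

## The simulators: what they emulate, and what they do not

`calibrate_kernel()` + `sample_kernel_process()` synthesize unit-variance
smooth stationary processes as convolutions of unit white Gaussian noise
with a normalized kernel (sum of squared taps = 1), over-generating noise
by one kernel support per edge so every retained sample sees the full
kernel (true stationary draws, no wrap-around). Three kernels:

* **gaussian** — output ACF `exp(-0.5*a*tau^2)`: the canonical null model
  of the parametric test. The width is analytic: a kernel with standard
  deviation `s` gives ACF `exp(-tau^2/(4 s^2))`, so `s = 1/sqrt(2a)`. (The
  source text's phrase for this relation does not match the standard
  parameterization; the analytic relation above is used and verified
  empirically by the calibration checks.)
* **laplace** — kernel `exp(-a|t|)`, output ACF `(1+a|tau|)exp(-a|tau|)`:
  exponential-tailed, the stress case for the Gaussian assumption.
* **sinc** — kernel `sin(bt)/(bt)`, output ACF `sinc(b*tau)`: long-range,
  oscillating correlations.

For laplace/sinc the width is calibrated to a target roughness by
root-finding on the *exact expectation* of the forward-difference roughness
computed from the kernel taps (`expected_roughness()`): for a standardized
stationary series `E var(diff x) = 2(1 - rho(dt))`, and the lag-1
autocorrelation of the sampled process equals that of the normalized taps.
This is the infinite-path limit of calibrating against an empirical average
over long paths, is deterministic, and is verified in the tests against the
empirical mean over 50 paths of 1e5 points (within 2%). Kernels are
truncated at ±6 width units (gaussian/laplace) or 40 lobes (sinc; its slow
decay needs the wide support); requests implying more than 2e7 taps are
rejected with guidance rather than exhausting memory.

Seed policy: one master seed per configuration; path `i` uses a stream at
a fixed increment `i - 1` from a multiplicatively spread base, so path `i`
is reproducible independently of `n_paths` and nearby master seeds give
unrelated streams. Everything downstream (experiments, acceptance script)
derives its seeds from these configs, making all reported numbers
bit-reproducible.

What the generator does **not** emulate: non-Gaussian driving noise,
genuine long-memory (fractional) processes, nonstationarity, measurement
noise floors, or cross-correlated path ensembles. Passing tests on these
simulations therefore demonstrate calibration *under the stated process
classes*, not under every real physiological signal; the wavelet module
narrows the gap for band-power pipelines, where Gaussian-like smoothing is
introduced by construction.

## Wavelet band power

`wavelet_power_series()` convolves a series with a unit-energy complex
Morlet kernel (`sigma_t = n_cycles/(2*pi*foi)`, truncated at 5 envelope
widths, no admissibility correction — negligible at 5+ cycles), squares the
magnitude, trims half a kernel width from each edge, and optionally takes
the fourth root, which brings the power's marginal distribution close to
Gaussian. More cycles produce smoother power series (lower roughness), and
roughness rises with the frequency of interest, so the ESS of band-power
correlations grows with frequency — the behavior that makes
frequency-resolved connectivity thresholds frequency-dependent.

One quantitative caveat, measured here across seeds and lengths: the
squared ACF of fourth-root band power has heavier shoulders than its
curvature-matched Gaussian, so the fitted half-width is systematically
~18% narrower than the sample half-width. The fit captures the main lobe
(and hence the ESS integral) well, but is not exact in shape; the tests
assert agreement at that measured level.

## Validation harness and problem sizes

`run_experiment()` scripts five studies (`roughness_recovery`,
`ess_comparison`, `null_calibration`, `robustness`, `timing`), each
emitting a tidy table and reproducible under its config seed. Default desk
scale is 500 paths of 2000 points — large enough that binomial error on a
5% rejection rate is ~1 percentage point — and the acceptance script uses
2000 pairs (Gaussian null) and 1000 pairs per non-Gaussian kernel; all
grids are config-overridable upward. The `timing` study reports medians of
repeated runs and is informational: only orderings (per-sample cost flat
in `n` for the parametric route, growing for the FFT route) are asserted,
never absolute times. Confidence intervals in the recovery study are
percentile intervals over replicate paths.

## Numerical choices and degenerate inputs

* Sample (n−1) variance throughout; the population/sample distinction is
  O(1/n) and irrelevant at the scales involved.
* Forward differences (not central) for the derivative; this matches the
  lag-1 identity `E var(diff) = 2(1 - rho(dt))` used for calibration, and
  its finite-`dt` expectation `2(1 - exp(-a*dt^2/2))/dt^2` is the
  reference in the recovery tests (the discretization bias is +O(a^2) and
  negligible for `a <= 0.1` at `dt = 1`).
* Constant series are rejected as degenerate everywhere (zero variance;
  roughness and correlation undefined). `|r| = 1` yields an infinite
  statistic and `p = 0` with a warning. A non-positive ACF-sum denominator
  (possible with noisy opposite-signed ACFs) returns `nu = n` with a
  warning rather than a negative ESS.
* The biased (1/n) ACF normalization with ≥2n zero-padding matches the
  `(n-k)/n` taper already present in the ACF-sum formula and avoids
  circular aliasing.

## Known limitations

* **Exponential-tailed ACFs are the failure mode.** For the
  Laplace-kernel process the true ACF-product integral is `5/(2a)` while
  the curvature-matched Gaussian gives `sqrt(pi)/a`: the parametric ESS
  overestimates `nu` by the constant factor `5/(2*sqrt(pi)) ≈ 1.41`
  regardless of roughness, and the measured type-I error at the 5% level
  is ~10% (2000-point pairs at roughness 1e-3). The kink of such ACFs at
  the origin is exactly where a second-order expansion is least valid.
  Signals suspected of exponential-like autocorrelation (for example
  fMRI-like dynamics) should be Gaussian-filtered first, or tested with
  the Welch-based reference. The long-range oscillating (sinc) case, by
  contrast, is benign: the theoretical overestimate is `sqrt(pi/3) ≈ 1.02`
  and measured rejection stays at the nominal level.
* **White noise is the opposite edge**: the per-sample derivative
  roughness of white noise is exactly 2, so `nu -> n*sqrt(2/pi) ≈ 0.80 n`
  and the parametric test is mildly conservative where the classical test
  is already valid. (The full-support FFT reference is worse there:
  accumulated ACF noise drives its `nu` toward `n/2`.)
* Very low roughness relative to the series length (fewer than ~20
  effective samples) biases every estimator upward — the variance floor of
  a variance estimate on few effective observations; the
  `roughness_recovery` experiment exposes this regime.
* Irregular sampling, trends, partial correlation, lagged
  cross-correlation, and regression residuals are out of scope.
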