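# tsess — correlation significance for autocorrelated time series

Correlating two time series and reading the p-value off the classical
Fisher-z test is one of the most common mistakes in physiological and
neuroimaging data analysis: `n` temporally dependent samples carry far fewer
than `n` degrees of freedom, and the uncorrected test can declare wildly
significant correlations between completely independent smooth signals.

`tsess` corrects the test through the **effective sample size (ESS)** ν —
the number of independent observations that would produce comparable test
statistics — and centres on a fast parametric ESS estimator. Under the null
that two series of length `n` with ESS ν are uncorrelated,

```
sqrt(nu - 3) * arctanh(r)  ~  N(0, 1).
```

The classical route estimates ν from the sample autocorrelation functions
(ACFs) ρ and γ:

```
nu = n / ( rho_0*gamma_0 + 2 * sum_k ((n-k)/n) * rho_k*gamma_k ),
```

which costs O(n log n) and accumulates noise over the lag sum. `tsess`
instead fits each ACF with the Gaussian form matched to its curvature at
zero lag (a Laplace approximation), `rho(tau) = exp(-0.5*lambda2*tau^2)`,
where the roughness `lambda2 = |rho''(0)|` equals the variance of the
temporal derivative of the standardized series. The ESS then has the closed
form

```
nu = n * sqrt( (var(dx) + var(dy)) / (2*pi) ),
```

computable in O(n) from forward differences. For smooth stationary signals
(wavelet band power, movement trajectories, smoothed neuroimaging signals)
this is both faster and less noisy than the ACF-sum route.

The package also provides: classical FFT- and Welch-based reference
estimators, a Rice zero-crossing variant, corrected significance quantiles,
pairwise connectivity matrices with optional Benjamini–Hochberg correction,
simulators for smooth Gaussian processes with Gaussian / exponential-tailed
(Laplace kernel) / long-range (sinc kernel) autocorrelation calibrated to a
target roughness, Morlet-wavelet band-power extraction with the fourth-root
transform, and a seeded experiment harness.

## Worked example

Two *independent* smooth processes (roughness 0.01, so roughly 6 effective
samples per 100) of length 2000:

```r
library(tsess)
spec  <- calibrate_kernel("gaussian", target_roughness = 0.01)
paths <- sample_kernel_process(spec,
           simulation_config(n = 2000, n_paths = 2, seed = 16))
corr_test(paths[[1]], paths[[2]])
#>         ESS-corrected correlation test
#>
#> pearson r = 0.1732, n = 2000, ESS nu = 120.05 (factor 0.0600, parametric)
#> Fisher z = 0.1750, statistic = 1.8928, two.sided p-value = 0.05838
#> 97.5% rejection threshold |r| > 0.1792

corr_significance(cor(paths[[1]]$values, paths[[2]]$values), 2000)$p.value
#> 5.361e-15   # the uncorrected test is catastrophically overconfident
```

The corrected test sees r = 0.17 between two independent smooth series for
what it is — about 120 effective samples, p ≈ 0.06 — while the uncorrected
test would report p ≈ 5e-15. The printed `q975` threshold is the smallest
|r| that would be declared significant at the 5% level for this pair.

Multi-channel analysis and simulation are available from the shell as well:

```sh
Rscript inst/cli/tsess.R simulate gaussian --roughness 0.01 --n 2000 --paths 8 --seed 1 --out paths.csv
Rscript inst/cli/tsess.R connectivity paths.csv --method parametric --mt bh
Rscript inst/cli/tsess.R validate null_calibration --reps 500 --n 2000 --roughness 0.01
```

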