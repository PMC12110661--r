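---
title: "Estimating the Hurst exponent of short, contaminated time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the Hurst exponent of short, contaminated time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkdfa)
```

## The problem

Many behavioral and physiological signals — mood ratings, stride
intervals, reaction times — show long-range temporal correlations: the
autocorrelation decays so slowly that observations hundreds of steps apart
remain dependent. The strength of that dependence is summarized by the
Hurst exponent $H \in (0,1)$: $H = 0.5$ is uncorrelated noise, $H > 0.5$
persistence, $H < 0.5$ anti-persistence. Estimating $H$ is routine for
long, clean laboratory series, but self-report and field data are short
(tens to hundreds of points) and contaminated by measurement noise,
nuisance oscillations and drifts. This package implements two estimators —
the Bayesian Hurst–Kolmogorov (HK) method and detrended fluctuation
analysis (DFA) of order 1 and 2 — together with an exact fractional
Gaussian noise (fGn) simulator, a library of contamination processes, and
a Monte Carlo harness that maps out which estimator is trustworthy under
which conditions.

## The fGn model and its exact simulation

fGn is the stationary Gaussian process with autocorrelation

$$\rho_k = \tfrac12\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right),$$

which `fgn_acf()` evaluates exactly; we never use the asymptotic
$H(2H-1)k^{2H-2}$ approximation, because at the short lags that dominate
short series the two differ materially.

`simulate_fgn()` draws exact Gaussian samples by circulant embedding
(Davies–Harte): the $n \times n$ Toeplitz autocovariance is embedded in a
circulant matrix of order $2(n-1)$, its eigenvalues are obtained by one
FFT of the first row, and a complex Gaussian vector shaped by
$\sqrt{\lambda_k}$ is transformed back. Numerical choices worth knowing:

* The output is population-standardized: mean 0 and variance 1 are exact
  *distributional* properties (the contaminant amplitudes below are
  defined against unit-variance processes), so no per-series empirical
  rescaling is applied.
* Eigenvalues below $-10^{-10}\max|\lambda|$ abort with an error naming
  $(H, n)$; values inside that band are floating-point zeros and are set
  to 0. On the benchmark grid ($H = 0.1..0.9$, $n \le 1024$) the spectrum
  is nonnegative, so this path never triggers there.
* The RNG is consumed in a documented order (frequency 0, then
  real/imaginary pairs for each positive frequency, then Nyquist), making
  the series a bit-reproducible function of `(H, n, seed)`.

## The HK estimator

For data $x$ modeled as fGn with unknown location and scale, placing the
noninformative prior $\pi(\mu, \sigma^2) \propto 1/\sigma^2$ and
integrating both out leaves the marginal posterior of $H$:

$$\ln\pi(h \mid x) \propto -\tfrac12\ln|R|
  - \tfrac{n-1}{2}\,\ln\!\big(e'R^{-1}e \cdot x'R^{-1}x - (e'R^{-1}x)^2\big)
  + \big(\tfrac n2 - 1\big)\ln e'R^{-1}e,$$

with $R = R(h)$ the exact autocorrelation matrix and $e$ the ones vector.
The bracket is nonnegative by Cauchy–Schwarz in the $R^{-1}$ inner
product, so the logarithm is always defined; the posterior is invariant
under affine transforms of the data, which the tests verify directly.
Only $H$ is sampled — location and scale are marginalized, not estimated.

Each evaluation needs $x'R^{-1}x$, $e'R^{-1}e$, $e'R^{-1}x$ and
$\ln|R|$. `toeplitz_forms()` computes all four in one $O(n^2)$ Durbin
recursion (implemented in C++): the prediction-error filters factorize
$R^{-1} = A'D^{-1}A$, so the quadratic forms accumulate as innovations of
$x$ and of $e$ weighted by prediction-error variances, and
$\ln|R| = \sum_k \ln v_k$. A nonpositive $v_k$ is reported as numerical
non-positive-definiteness and maps to $-\infty$ log-density rather than a
wrong value.

`sample_hk_posterior()` draws $H$ by accept–reject with a Uniform(0,1)
proposal. The envelope $\ln M$ is found by bounded scalar optimization on
$[10^{-6}, 1-10^{-6}]$ (absolute tolerance $10^{-6}$ in $h$) plus a
$10^{-9}$ safety margin; a proposal $h$ is accepted when
$\ln u \le \ln\pi(h \mid x) - \ln M$. The point estimate
(`estimate_h_hk()`) is the median of 100 posterior draws — enough that
more draws no longer improve accuracy, cheap enough for Monte Carlo use.
The sampler has a hard budget of $10^6$ proposals; exhausting it raises an
error carrying the envelope value and the best rejected log-density
instead of silently returning fewer draws. With a uniform proposal the
acceptance rate roughly equals the posterior's effective width, so it
falls with $n$ (about 10% at $n = 256$); the budget is far above anything
seen on the benchmark grid.

## DFA

DFA estimates $H$ from the scaling of detrended fluctuations of the
profile $y_i = \sum_{k\le i}(x_k - \bar x)$ (`build_profile()`). For each
bin size $s$ the profile is cut into $\lfloor n/s\rfloor$ non-overlapping
windows from the start — the trailing remainder is discarded, and there is
no reversed second pass — a polynomial of degree 1 (DFA1) or 2 (DFA2) is
removed per window, and

$$f(s) = \sqrt{\frac{1}{N_s}\sum_v \frac{1}{s}\sum_i r_{v,i}^2}$$

is the double-averaged RMS residual. $f(s) \sim s^H$, so `h_hat` is the
least-squares slope of $\ln f$ on $\ln s$ (the log base is irrelevant).

The default scale set is the arithmetic sequence $4, 8, 12, \ldots \le
n/2$ — the conventional bin-size range $[4, N/2]$. Whether small scales
should be excluded (e.g. restricting to $[8, N/10]$) is a live
methodological question; the `scales` argument of `estimate_h_dfa()`
accepts any override, but the default follows the common convention.
Window fits use the within-window centered index as regressor purely for
conditioning; residuals are identical to the raw-index fit, which the
brute-force oracle test confirms at $10^{-12}$.

## Contamination models

`contaminate()` mixes a contaminant into a base series at amplitude
$A \in [0,1]$:

| kind | added term | parameters |
|---|---|---|
| `awgn` | $A u_t$, iid N(0,1) | — |
| `fgn` | $A p_t$, fGn with $H_c$ | `Hc = 0.9` |
| `short_range` | $A s_t$, fractionally integrated AR(1) | `d = 0.25`, `a1 = 0.1` |
| `cyclical` | $A \sin(2\pi t/\tau)$ | `tau = 365` or `36500` |
| `linear` | $\pm A\,(0.005\,t)$ | `sign` |
| `quadratic` | $\pm A\,(0.000005\,t^2)$ | `sign` |

Design choices that required judgment:

* **Cyclical trend over the running index.** The harmonic is evaluated at
  $t = 1..n$; evaluated at the constant $n$ it would be a constant offset,
  not a trend. With $\tau = 365$ the cycle is comparable to the series
  length (a seasonal cycle in daily data); $\tau = 36500$ is two orders
  slower, a drift-like curvature.
* **Short-range structure as ARFIMA.** The short-range contaminant is
  defined by an AR(1) filter combined with a fractional difference
  $(1-B)^d$, $d = 0.25$. The printed recursion is ambiguous about which
  side the AR term enters; we implement the standard ARFIMA(1, d, 0)
  reading — AR(1) core, then fractional integration $(1-B)^{-d}$ via its
  MA($\infty$) coefficients $\psi_j = \Gamma(j+d)/(\Gamma(j+1)\Gamma(d))$
  truncated at the available history — and validate the result against an
  independently truncated MA($\infty$) autocorrelation oracle.
* **Standardization.** The fractionally integrated AR(1) does not have
  unit population variance, so `gen_short_range()` standardizes its
  output empirically (after a 1000-sample burn-in); `awgn` and `fgn`
  contaminants already have unit population variance and are left alone.
  This keeps the meaning of $A$ comparable across kinds.
* **1-based trend index**, so the full-amplitude linear trend reaches
  $0.005\,n$ at the last observation (2.56 at $n = 512$).

## The Monte Carlo harness

`run_cell()` runs one condition — (estimator, $H$, $n$, contaminant, $A$)
— for `n_reps` replicates. Per replicate it derives three seeds from the
master seed and the cell identity with a platform-stable polynomial hash
(`substream_seed()`): one for the base fGn series, one for the
contaminant (so the contaminant never duplicates the base series' draws),
one for the estimator. The cell summary reports the mean and SD of the
estimates and a normal-approximation 95% interval for the mean,
$\bar h \pm 1.96\,s/\sqrt{m}$ (a percentile interval over replicate
estimates is available via `ci = "percentile"`). Replicates whose
estimator errors are excluded and counted in `n_failures`; a cell with
more than 10% failures reports `NA` summaries rather than a biased mean.

`run_grid()` crosses the axes of a `run_config()` and writes one CSV row
per cell; because every cell is seeded from its own identity, the output
is a pure function of the configuration, independent of execution order,
and an interrupted run resumes by skipping rows already on disk. The
default `n_reps = 200` keeps a full grid desk-scale; a 1000-replicate
benchmark is just a config change and the harness accepts the full
9 × 6 × 11 grid (1782 cells per contaminant family across the three
estimators).

`decision_map()` condenses a results table into a verdict per condition:
the estimator with the smallest $|\bar{\hat H} - H|$, provided that error
is at most 0.1 (in Hurst units), else `"none"`; exact ties break in the
order HK, DFA1, DFA2, reflecting the preference for the method whose
accuracy degrades most gracefully on short series.

## What the generator does and does not emulate

The synthetic conditions are exactly the benchmark's study conditions:
exact Gaussian fGn bases, the six contaminants above, amplitudes in
$[0,1]$, lengths 32–1024, $H$ from 0.1 to 0.9. Real behavioral data
additionally feature non-Gaussian marginals, missing samples, outliers,
regime shifts and multiplicative noise — none of which are modeled here.
Passing tests therefore certify the estimators' behavior under the stated
contamination models, not under every field condition.

## Numerical and testing choices

* **Fidelity checks use known-mean, known-variance autocorrelation
  estimates.** The simulator's output has population mean 0 and variance
  1 by construction, so tests estimate $\rho_k$ as
  $\sum_t x_t x_{t+k} / (n-k)$, which is unbiased. The familiar
  mean-centered sample ACF carries a negative bias of order $n^{2H-2}$
  under long-range dependence (≈0.11 at $H = 0.8$, $n = 256$) — a
  property of that estimator, not of the simulator — and would mask
  exactly the agreement the check is after. The same reasoning applies to
  second-moment checks.
* **Monte Carlo scales.** The test suite uses 200 replicates for recovery
  checks, 500–1000 for moment and direction checks, and the shipped demo
  grid uses 5 — sizes chosen so the whole suite runs on a laptop in
  minutes while keeping Monte Carlo error well inside each asserted
  tolerance.
* **Degenerate inputs** are errors, not warnings: constant series (zero
  variance) for the HK method, zero fluctuations for the DFA fit,
  non-positive-definite autocorrelation matrices, series shorter than 8
  (HK) or 16 (DFA).
* **Determinism contract.** Every stochastic function takes an explicit
  seed and restores the caller's RNG state; the CLI, the grid and the
  decision map reproduce byte-identical outputs from the same inputs.

## Known limitations

* The HK estimator assumes the fGn family; under strong trends its
  posterior concentrates near the upper boundary and the point estimate
  saturates toward 1 rather than diverging (unlike DFA1, whose fitted
  slope can exceed 1). That boundary behavior is informative in the
  decision map but should not be read as an unbiased estimate.
* $H \ge 1$ regimes (nonstationary signals) are out of scope; so are
  adaptive DFA variants, multifractal extensions and crossover detection.
* The accept–reject sampler is exact but its cost grows with $n$
  (posterior width shrinks); for $n \gg 10^3$ an MCMC scheme would be
  preferable, and is deliberately not provided here.
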