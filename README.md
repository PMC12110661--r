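# hkdfa

Hurst exponent estimation for **short, noisy time series**, built for the
kind of data behavioral and physiological research actually produces:
a few dozen to a few hundred observations, contaminated by measurement
noise, nuisance oscillations and drifts.

Long-range temporal correlation strength is summarized by the Hurst
exponent *H* ∈ (0, 1): *H* = 0.5 is uncorrelated noise, *H* > 0.5
persistence, *H* < 0.5 anti-persistence. The package provides two
estimators and the machinery to decide between them:

* **The Bayesian Hurst–Kolmogorov (HK) method.** Modeling the data as
  fractional Gaussian noise (fGn) with autocorrelation
  ρ<sub>k</sub> = (|k+1|<sup>2H</sup> − 2|k|<sup>2H</sup> +
  |k−1|<sup>2H</sup>)/2 and integrating location and scale out under a
  noninformative prior leaves the marginal posterior

  ln π(h | x) ∝ −½ ln|R| − ((n−1)/2) ln(e′R⁻¹e · x′R⁻¹x − (e′R⁻¹x)²)
  + (n/2 − 1) ln e′R⁻¹e,

  with R = R(h) the fGn autocorrelation matrix and e the ones vector.
  The quadratic forms and log-determinant come from one O(n²) Levinson/
  Durbin recursion (C++); *H* is sampled by accept–reject with a
  Uniform(0,1) proposal, and the point estimate is the median of 100
  posterior draws.
* **Detrended fluctuation analysis (DFA1, DFA2).** RMS residuals f(s) of
  a polynomially detrended cumulative profile over bin sizes
  s = 4, 8, 12, … ≤ n/2; the slope of ln f on ln s estimates *H*.
* **An exact fGn simulator** (Davies–Harte circulant embedding), **six
  contamination models** (white noise, persistent fGn, fractionally
  integrated AR(1) short-range correlations, cyclical / linear /
  quadratic trends), and a **Monte Carlo harness** that benchmarks the
  estimators over grids of (H, N, amplitude) and emits a per-condition
  **decision map**: the most accurate estimator, or "none" when no method
  reaches |mean estimate − H| ≤ 0.1.

## Worked example

```r
library(hkdfa)

x <- simulate_fgn(0.8, 128, seed = 7)        # persistent fGn, 128 samples
sample_hk_posterior(x, n_samples = 100, seed = 42)
#> HK posterior: 100 draws, point estimate (median) = 0.8412
#>   acceptance rate 0.129 (775 proposals), log M = -280.4497

estimate_h_dfa(x, order = 1)
#> DFA1 estimate: h = 1.0297 (n = 128, 16 scales in [4, 64])
```

Both methods see the same 128 persistent samples (true H = 0.8). The HK
posterior median lands at 0.84; DFA1 overshoots to 1.03 — the typical
short-series failure mode that motivates the HK method. Contamination
pulls estimates toward the contaminant's own exponent:

```r
y <- contaminate(x, contaminant_spec("awgn", amplitude = 0.5), seed = 9)
estimate_h_hk(y, seed = 43)
#> [1] 0.7079829                  # white noise dilutes persistence
```

Monte Carlo benchmarking and the decision map:

```r
cell <- run_cell("HK", 0.8, 64, contaminant_spec("awgn", 0),
                 n_reps = 50, master_seed = 1)
cell$mean_hhat                   # 0.8068 — |bias| ~ 0.007 at N = 64
#> [1] 0.8068123

cfg <- read_run_config(system.file("extdata", "demo-config.txt",
                                   package = "hkdfa"))
res <- run_grid(cfg, out = "demo-results.csv")
decision_map(res, threshold = 0.1)
```

Per-cell rows report the replicate mean, SD and a 95% CI of the mean
estimate plus a failure count; the decision map reduces each
(contaminant, H, N, A) condition to the best estimator under the 0.1
accuracy criterion.

## Command line

A thin Rscript wrapper over the same functions ships in `exec/hkdfa`
(after installation: `system.file("exec", "hkdfa", package = "hkdfa")`):

```sh
hkdfa simulate --hurst 0.7 --length 256 --seed 42 --out series.txt
hkdfa contaminate series.txt --kind linear --amplitude 1 --sign 1 --out noisy.txt
hkdfa estimate noisy.txt --method hk --seed 1
hkdfa experiment --config inst/extdata/demo-config.txt --out results.csv
hkdfa decision-map results.csv --threshold 0.1 --out decisions.csv
```

Series files are plain text, one value per line (single-column CSV with a
header also accepted). Each command ends with a stable one-line
`key=value` record for shell pipelines and exits nonzero on any error.

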