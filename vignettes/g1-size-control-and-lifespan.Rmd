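---
title: "G1 kinetics, size control and lifespan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G1 kinetics, size control and lifespan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g1span)
library(dplyr)
```

g1span estimates the kinetic determinants of the budding-yeast G1 phase,
quantifies how strongly G1 growth depends on birth size, fits protein
half-lives from chase experiments, and compares lifespan cohorts and
genome-wide strain panels. This vignette explains the models behind each
stage, the defaults and why they were chosen, what the synthetic-data
generators do and do not emulate, and the numerical choices that matter.

## The G1 model

A newborn daughter cell of volume $V_b$ (fL) grows exponentially at specific
rate $k$ (h$^{-1}$) until it reaches its critical size $V_c$, the volume at
which half of a synchronous culture has budded; budding marks commitment to
a new round of division. Three quantities follow:

$$ kT_{G1} = \ln\frac{V_c}{V_b}, \qquad T_{G1} = \frac{\ln(V_c/V_b)}{k}. $$

$kT_{G1}$ is the relative growth in G1 (dimensionless, a natural-log
ratio), and $T_{G1}$ the absolute G1 duration in hours. `summarize_g1()`
enforces these identities exactly; when an estimated $V_c$ falls below
$V_b$ the duration is reported as 0 with a flag rather than a negative
time.

The three inputs come from different measurements:

* **Growth rate `fit_growth_rate()`** — ordinary least squares of
  $\ln(\text{mean volume})$ on time in a synchronous (elutriated) culture.
  Only time points with budded fraction at or below `max_budded` (default
  0.5) enter the fit: once most of the culture is past Start the mean
  volume no longer reflects G1 growth. The 0.5 default is a design choice —
  the measurement itself does not dictate a cutoff — and is exposed as an
  argument.
* **Critical size `estimate_critical_size()`** — the budding-index curve
  rises sigmoidally with volume; points with budded fraction inside
  `window` (default `c(0.1, 0.9)`, the approximately linear portion) are
  fit by least squares of budded fraction on volume, and $V_c$ is the
  volume where the fitted line crosses 0.5. The estimate is clamped to the
  volume range of the points used, and is invariant to affine rescaling of
  the volume axis.
* **Birth size `estimate_birth_size()`** — daughters are the smallest
  cells of an asynchronously dividing population, so the default estimator
  smooths the volume histogram with a cubic smoothing spline and returns
  the first local maximum scanning from the smallest bin. The smoothing
  parameter is expressed as a bandwidth in fL (default two bin widths,
  converted to spline degrees of freedom as range/bandwidth); a small
  prominence threshold (5% of the global density maximum) keeps smoothing
  ripples in the sparse tail from being mistaken for the newborn mode. If
  the smoothed density is monotone, the estimator falls back to a
  percentile of the cumulative histogram (default 5%, linearly
  interpolated within the bin) with a warning. Both methods are exposed;
  the smallest-mode default is a documented stand-in for newborn-peak
  readings of channelyzer histograms, not a reimplementation of any
  particular published algorithm.

Units are fixed: volumes in fL, growth times in hours, chase times in
minutes.

## Size control

Plotting $kT_{G1}$ against $\ln(V_b/V_{ref})$ measures the efficiency of
size control: a slope of 0 means G1 growth is independent of birth size (a
"timer"), a slope of $-1$ means the critical size is independent of birth
size (a perfect "sizer"), and wild-type daughters sit near $-0.7$.
`size_control_fit()` uses plain ordinary least squares (matching how such
slopes are conventionally obtained from spreadsheet linear fits), reports a
normal-theory 95% CI, and `classify_size_control()` turns the CI into one
of `no_size_control`, `perfect_sizer`, `partial_sizer` or `anomalous`.

Two numerical points matter. First, both axes are *natural*-log
quantities: $kT_{G1}$ is a natural-log ratio by construction, and using
base-10 on the size axis would rescale the slope by $\ln 10$ and destroy
comparability with the $-0.7$ benchmark; a unit test pins this. Second,
$V_{ref}$ (default: the panel median birth size, standing in for wild
type) shifts only the intercept — the slope is invariant, which is also
tested. No per-strain precision weighting is applied; the fit treats every
strain or cell as one point.

```{r sizecontrol}
cells <- sim_daughter_cells(1000, exponent = -0.7, noise_sd = 0.1, seed = 3)
fit <- size_control_fit(cells)
tidy(fit)
classify_size_control(fit)
```

## Protein decay

`fit_decay()` normalizes target band densities pointwise by the loading
control, rescales to the first time point, and fits
$\ln(\text{density})$ on time by least squares; the decay constant is
$-$slope and $t_{1/2} = \ln 2/\lambda$. Log-linear least squares rather
than nonlinear fitting is deliberate: on densitometry data it matches the
conventional "fit an exponential" reading, is deterministic, and is exact
on any noiseless exponential regardless of the sampling grid (a tested
invariant). The intercept is left free rather than forced through the
$t=0$ point. Non-positive normalized densities are dropped with a warning;
a non-positive decay constant yields a `no_decay` flag and an infinite
half-life instead of a misleading number.

## Lifespan statistics

`survival_curve()` and `lifespan_summary()` are Kaplan–Meier based
(via the survival package): with no censoring — the replicative-lifespan
convention, where every mother is followed to death — the curve equals the
empirical survivor function and the mean is the arithmetic mean; with
censoring the mean falls back to the restricted mean up to the largest
observed time and is flagged as a lower bound. The median and the age of
90% mortality are read from the curve as the smallest time at which
survival reaches 0.5 and 0.1.

`logrank_test()` is the standard two-group Mantel–Cox test.
`wang_allison_test()` addresses *maximum* lifespan: every animal is
classified as above versus at-or-below the pooled 90th-percentile
lifespan, and the 2×2 group-by-class table is tested with an ordinary
Pearson $\chi^2$ without continuity correction. The quantile convention —
pooled, order statistic at $\lceil qn \rceil$, ties assigned to the lower
class — is a documented choice (the test's users rarely state one) and is
configurable through `q`. Because the "above" class is small by
construction, the test is conservative on discrete lifespans; the suite
verifies a type-I error within [0.02, 0.08] at $\alpha = 0.05$, against
[0.03, 0.07] for the log-rank test, over 2000 null simulations of
50-cell-per-group cohorts.

## Strain-panel comparisons

`compare_groups()` runs, per variable, a two-sided Mann–Whitney test and a
Welch $t$ test between the long-lived (LL) and not-long-lived (NLL)
classes, dropping missing values pairwise. The Mann–Whitney p-value is
exact (null distribution of $U$) when $\min(n_x, n_y) \le 8$ and there are
no ties — beyond that the enumeration buys nothing — and otherwise uses the
normal approximation with tie-corrected variance and continuity
correction; the two branches agree to $|\Delta p| < 0.02$ at $n = 8+8$.
Raw p-values are reported by default, matching common practice for these
panel summaries; Benjamini–Hochberg adjustment is available via
`adjust = "BH"`.

`logistic_rank()` fits a binary logistic regression of class membership on
the panel variables by maximum likelihood (IRLS, convergence 1e-8, at most
100 iterations) and orders predictors by Wald p-value. Predictors are
z-scored by default so the *coefficients* are comparable across variables;
Wald p-values, and hence the ranking, are unaffected by this rescaling,
and `standardize = FALSE` recovers raw-scale coefficients (for a single
binary predictor the coefficient then equals the 2×2 log odds ratio, a
tested oracle). Complete separation is flagged, never silently reported.

`hexbin_summary()` (a pointy-top hexagonal tiling with `gridsize`
hexagons across x, built on the classic two-offset-lattice assignment) and
`kde_summary()` summarize dense panels for plotting; hexagon counts are
conserved and translation-invariant.

## What the generators emulate

Every input has a seeded generator, so the full pipeline runs with no
external data. The defaults are the package's calibrated study
conditions, chosen once:

* `sim_elutriation()` / `sim_strain_panel()` — exponential growth from
  $V_b = 40$ fL at $k = 0.35$ h$^{-1}$ toward $V_c = 64$ fL
  ($kT_{G1} = \ln 1.6 \approx 0.47$), with the budding transition a
  logistic in volume centred at $V_c$ with width 8 fL (smooth, invertible,
  and matching the observed sigmoidal rise). Between-strain and
  between-cell birth sizes are lognormal with $\sigma_{\log} = 0.15$,
  a realistic spread for daughter populations. Measurement noise is
  multiplicative lognormal-like on volumes (channelyzer noise structure is
  not documented anywhere authoritative; multiplicative is assumed and
  configurable).
* `sim_size_histogram()` — a two-component lognormal mixture whose tight
  newborn component has its mode at $V_b$ (weight 0.25) under a broader
  dividing-population component (mode at $1.8 V_b$), which is exactly the
  feature the smallest-mode estimator reads.
* `sim_decay()` — presets `decay-untreated` (28 min) and
  `decay-ibuprofen` (10 min) reproduce the half-life contrast the decay
  stage is calibrated against.
* `sim_lifespan_cohort()` — a discrete Gompertz hazard
  $q(d) = 1 - e^{-q_0 e^{gd}}$ with $q_0 = 0.005$, $g = 0.15$, giving mean
  lifespans near 20–25 divisions, typical of wild-type replicative
  lifespan; no mortality model is prescribed by the data themselves, so
  the standard aging-demography choice is used and fully exposed. Sampling
  inverts the closed-form cumulative hazard, so the $g = 0$ geometric
  special case is available as an analytic oracle.
* `sim_strain_table()` — 137 LL vs 3842 NLL strains with LL birth size
  shifted $-5\%$ and fitness $-2\%$ at a 10% within-class CV; the class
  sizes mirror genome-wide panels and the shift directions encode "LL
  mutants are slightly smaller at birth and less fit", with magnitudes
  chosen to be small but detectable at panel scale.

What they do **not** emulate: mother-cell size inflation across divisions,
counting statistics of radiolabel assays, real channelyzer binning
artifacts, correlated measurement error across time points, or missingness
patterns of genome-wide tables. Passing round-trip tests therefore shows
the estimators are correct on data satisfying the model assumptions — not
that real cultures satisfy them.

## Problem sizes and determinism

The test suite and the acceptance script use: 20-strain panels and
1000-cell cohorts for slope recovery, $10^4$ draws for the G1 identity,
2000 null replicates for test calibration, 100 replicates of the
137 + 3842 strain table for predictor-ranking recovery, and $10^5$-sample
Monte Carlo oracles for the lifespan generator — sizes at which every
stochastic check has comfortable margin while the whole suite runs in
about half a minute. All generators draw through `withr::with_seed`, so
results are bit-identical for a given seed and the caller's RNG stream is
never disturbed; `run_pipeline()` serializes floats at 6 significant
digits so identical configurations produce byte-identical reports.

## Known limitations

* The birth-size estimator is a documented stand-in (see above); on
  histograms whose newborn peak is not separated from the population bulk
  it will fall back to the percentile method.
* The size-control fit is plain OLS: no errors-in-variables correction,
  so strong noise on estimated $V_b$ attenuates the slope toward zero.
* `wang_allison_test()` ignores censoring flags (it classifies observed
  lifespans); heavily censored cohorts need the log-rank test instead.
* The logistic ranking assumes linear log-odds in the standardized
  predictors and fits no interactions.
```
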