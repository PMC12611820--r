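---
title: "Mixed entropic-expectation flows: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed entropic-expectation flows: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixedflow)
```

## The model

A recorded signal (for example the normalized first principal component of a
cortical region's calcium activity) induces a marginal probability density
$q(x)$. This package describes how such densities are reshaped by gradient
flows of two functionals on the manifold of smooth, positive, unit-mass
densities:

* **Entropy** $S[q] = -\int q \log q \, dx$. Its projected gradient field is
  $v_S = \log q - \langle \log q \rangle$, where
  $\langle \log q \rangle = \int q \log q \, dx$; the mean subtraction keeps
  the flow tangent to the normalization constraint. The finite
  transformations generated by $v_S$ are power-law renormalizations
  $q \mapsto q^\lambda / \int q^\lambda dx$.
* **Expectation** $E[q] = \int x\, q\, dx$, with projected field
  $v_E = x - \langle x \rangle$. Its finite transformations are exponential
  tilts $q \mapsto q\, e^{\lambda x} / Z$, which shift a Gaussian's mean by
  $\lambda \sigma^2$ at constant variance.

For a density symmetric about its mean the two fields are orthogonal:
$\mathrm{Cov}_q(\log q, x) = 0$ (`orthogonality_covariance()`), so entropy
and expectation act as independent basis directions there. The **mixed
flow** combines them,

$$\frac{\partial \log q}{\partial \lambda}
  = \alpha\,(\log q - \langle \log q \rangle) + \beta\,(x - \langle x \rangle),$$

with a dimensionless entropy coefficient $\alpha$ and an expectation
coefficient $\beta$ (units 1/signal). **Sign convention:** the entropic
field is used exactly as written above, so along increasing $\lambda$ a
positive $\alpha$ drives the power-law exponent up ($e^{\alpha\lambda} > 1$)
and *sharpens* the density, while negative $\alpha$ widens it. The gradient
of $S$ could equally be written with the opposite sign (the first variation
of $-\int q\log q$ is $-(1+\log q)$); we fix the convention once, document
it here and in `?flow_params`, and use it consistently in every flow,
fitting and simulation routine, so fitted coefficients are always
interpretable against it.

Applied between two signals, the same operator gives a directed time-series
predictor

$$\hat x_B = x_A + \alpha\,[\log q_A(x_A) - \langle \log q_A \rangle]
  + \beta\,[x_A - \langle x_A \rangle],$$

the form fitted by `flow_fit()`. At $\alpha = \beta = 0$ it is the identity
map; both correction terms are centered over the training samples.

## Density representation and numerics

Densities live on uniform 1-D grids (`density_grid`), 1024 points spanning
the inducing sample's mean $\pm 8$ SD by default, with trapezoidal
quadrature. Mass values are floored at $10^{-300}$ before any logarithm, so
$\log q$ is always finite. Every operation that returns a density
renormalizes, keeping the trapezoidal mass at 1 to within $10^{-8}$ by
construction.

The mixed flow is integrated by explicit Euler on $\log q$ with per-step
renormalization and a default step $|\Delta\lambda| \le 0.01$: the flow is
stated as a derivative of the log density, and renormalizing each step
enforces unit mass exactly along the whole trajectory. Two exactness
properties pin the integrator down in tests: with $\alpha = 0$ the log-Euler
steps telescope and reproduce the exponential tilt to machine precision for
any step count, while with $\beta = 0$ the first-order error against
$q_0^{\exp(\alpha\lambda)}/Z$ halves as the step halves. Power-law and tilt
maps themselves are computed in log space with max subtraction, so large
exponents neither overflow nor underflow. A tilt that pushes more than 1% of
the mass into a boundary grid cell triggers a warning, since the finite
support then truncates the transformation.

## Density estimation

Empirical densities come from Gaussian-kernel KDE (`kde_model`), evaluated
as exact log-sum-exp mixtures so log-densities are finite everywhere. The
default bandwidth is the robust Silverman rule
$0.9 \min(\mathrm{SD}, \mathrm{IQR}/1.34)\, n^{-1/5}$; fluorescence-derived
signals are frequently heavy-tailed, and the interquartile term keeps
outliers from inflating the bandwidth. The classical normal-optimal variant
$1.06\,\mathrm{SD}\, n^{-1/5}$ differs only by a constant factor and is
available via `rule = "normal"`. The centering constant
$\langle \log q_A \rangle$ in the predictor is the sample mean of the KDE
log-density over the training samples (not a grid integral), matching the
fact that fitting happens on observed time points.

## Comparing densities

Three metrics score recovered against ground-truth densities:

* `wasserstein2_sq()`: squared 2-Wasserstein distance by inverse-CDF
  quadrature at 4096 quantile levels — exact for 1-D transport up to
  quadrature error; for Gaussians it equals $(\Delta\mu)^2 +
  (\Delta\sigma)^2$, which the tests use as an oracle.
* `total_variation()`: $\tfrac12 \int |p - q|\, dx \in [0, 1]$.
* `l2_distance()`: the function-space norm $(\int (p-q)^2 dx)^{1/2}$.
  "L2 error" is ambiguous between function-space and pointwise-mean
  readings; for densities we always report the function-space norm, and for
  time series the root-mean-square error, labeled `rmse`, so the two are
  never conflated.

## Fitting

`flow_fit()` minimizes the mean squared prediction error over
$(\alpha, \beta)$ with derivative-free Nelder-Mead from the neutral start
$(0,0)$ — the identity map — polished by box-constrained L-BFGS-B
(numeric gradients, bounds $|\alpha|, |\beta| \le 10^3$, objective
tolerance $10^{-10}$). The training objective is quadratic in the
coefficients, so the optimizer's solution can be (and in the tests is)
cross-checked against closed-form least squares on the two basis columns.
The best objective value seen is recorded after every evaluation; the trace
is non-increasing by construction and kept in the fit object.

Fitting is on the raw signal scale by default: the generative model used for
construct validation (`generate_pair_from_flow()`) is then exactly nested in
the fit family, which is what makes noiseless recovery exact and the
benchmark interpretable. Z-scoring with training-segment statistics is
available (`standardize = TRUE`) and is the default inside
`pairwise_analysis()`, where inputs are normalized principal-component
signals anyway and comparable scales across regions are wanted. Constant
series are rejected by `flow_fit()` but skipped with a record in batch mode.

## Validation and significance

`holdout_validate()` fits on the first 80% of both series and scores
$R^2$ on the held-out remainder, using only training-derived density and
centering constants. `random_cv()` repeats this over 20 random splits; each
test segment is a contiguous circular block rather than a pointwise random
subset, because regional signals are strongly autocorrelated and scattered
test points would leak training information through their neighbors
(pointwise mode remains available). The report carries the mean and SD of
the train-minus-test $R^2$ gap.

`circular_permutation_test()` builds the null by circularly shifting the
*source* series (the transformation's input) with uniform random offsets in
$[1, T-1]$ and refitting both coefficients for every surrogate; shifts are
drawn within sessions when session boundaries are declared, so surrogates
never mix recording sessions. Circular shifts preserve the marginal and the
autocorrelation of the source while destroying its alignment with the
target. Because a shift merely permutes the source values, the surrogate's
kernel density, bandwidth and centering constants equal the unshifted ones;
the implementation exploits this identity by rotating the precomputed
predictor basis, and a regression test confirms surrogate fits coincide
with from-scratch refits on shifted series. The p-value is the plain
proportion of surrogate $R^2$ at or above the empirical value; the
conservative $(k+1)/(n+1)$ variant is available via `p_method`.

`bh_fdr()` applies Benjamini-Hochberg step-up control (through
`stats::p.adjust`, verified in tests against a hand-run step-up oracle) and
`bonferroni()` the familywise bound. `pairwise_analysis()` pools all
off-diagonal ordered pairs — across recordings, when several are passed
jointly — into a single correction family at $q = 0.01$.

## Synthetic benchmarks

Two forward-generative experiments validate parameter recovery end to end.
Their defaults are fixed benchmark conditions, not tuning knobs:

* **Gaussian diffusion, density space.** Samples at time $t$ follow
  $N(0, 1 + 2Dt)$ with $D = 0.25$, $t_1 = 0$, $t_2 = 1$, $n = 20{,}000$
  samples. The KDE of the $t_1$ sample is flowed under the true
  $(\alpha, \beta) = (0.05, 0.5)$ to define the ground-truth target; a
  fresh sample of size $n$ is drawn from that target (inverse-CDF) and
  re-estimated by KDE, and the coefficients are recovered by minimizing the
  density-space L2 distance (`run_density_recovery()`). Because the
  observed target carries one extra round of kernel smoothing, the model
  density is convolved with the target's estimation kernel before the
  comparison (`fit_density_flow(kernel_sd = )`); omitting this
  measurement-error correction biases $\hat\alpha$ low by roughly half.
  With the correction $\hat\alpha$ is unbiased, and its remaining ~25%
  relative scatter reflects KDE sampling error at $n = 20{,}000$ against a
  small true $\alpha$.
* **Langevin series, time domain.** An Ornstein-Uhlenbeck process with
  sinusoidal drift ($\gamma = 1$, $a = 1$, $\omega = \pi$ rad/s,
  $\sigma = 0.3$, $dt = 0.01$, 50 s) provides an autocorrelated,
  non-Gaussian source; the target is the mixed-flow prediction under the
  true coefficients plus observation noise of SD $0.05 \times$ signal SD
  (`run_series_recovery()`). Recovery is by time-domain MSE. The
  trajectory-level total variation compares KDE value-distributions of the
  noiseless ground-truth target and its reconstruction under the fitted
  coefficients on a shared grid.

Benchmark summaries use medians over 20 seeded replicates; the same
conditions and replicate count are used by the test suite and the
acceptance script, each full benchmark completing in a few minutes on one
CPU.

What the generators emulate: smooth unimodal marginals, autocorrelated
sources, targets constructible exactly from sources by the predictor, and
controlled observation noise. What they do not emulate: non-stationarity,
inter-regional lags, shared global fluctuations, photobleaching or motion
artifacts, and multimodal marginals. Passing these benchmarks therefore
demonstrates estimator correctness and calibration under the model's
assumptions, not robustness of real-data conclusions to violations of
those assumptions.

## Data ingestion

Recordings load from headered CSV (first column time, one labeled column
per region); pixel-by-time stacks are taken as in-memory matrices with a
region mask, with NA pixels dropped (and counted) before the first
principal component is extracted. Binary container formats are deliberately
not parsed here — converting upstream exports to the CSV layout is a
one-liner in any analysis environment, and keeping ingestion plain-text
keeps the package dependency-light. The PC sign is fixed by non-negative
correlation with the regional mean trace, and the component is z-scored;
sampling interval and session boundaries travel as metadata and are never
resampled (stimulus alignment is upstream preprocessing).

## Known limitations

Only 1-D marginal densities are modeled; the flow machinery exposes just
the entropy and expectation functionals (the generalized-functional hook
exists but no other functional is implemented or tested). The predictor has
no lag or latent-state structure, so delayed coupling loads onto the
instantaneous terms. At realistic sample sizes the entropy coefficient is
estimated with substantially more variance than the expectation
coefficient, since it is identified only through curvature of the
log-density; interval statements about $\alpha$ should lean on the
permutation and cross-validation machinery rather than point estimates.
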