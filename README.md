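# mixedflow

Information-theoretic gradient flows for directed signal transformation
between brain regions.

Neural population activity can be summarized by the probability density of
a regional signal (for example the first principal component of ΔF/F
calcium traces in a visual area). As activity propagates between regions,
those densities are reshaped. `mixedflow` models the reshaping as a
gradient flow on the manifold of normalized densities, driven by two
interpretable functionals:

- **entropy**, whose projected gradient field `v_S = log q − ⟨log q⟩`
  generates power-law renormalizations `q ↦ q^λ / ∫ q^λ dx` and reshapes
  the spread of the density;
- **expectation**, whose field `v_E = x − ⟨x⟩` generates exponential tilts
  `q ↦ q e^{λx} / Z` and shifts its mean.

For densities symmetric about their mean the two flows are orthogonal
(`Cov_q(log q, x) = 0`), so their mixture

```
∂ log q / ∂λ = α (log q − ⟨log q⟩) + β (x − ⟨x⟩)
```

decomposes a transformation into an entropy-driven component (coefficient
α) and an expectation-driven component (β). Applied between two
simultaneously recorded signals, the operator becomes a directed
time-series predictor,

```
x̂_B = x_A + α [log q_A(x_A) − ⟨log q_A⟩] + β [x_A − ⟨x_A⟩],
```

whose coefficients are estimated by L2 loss minimization. The package is
aimed at researchers analyzing multi-region continuous recordings
(calcium imaging, LFP, any modality reducible to regional time series) who
want to quantify *how* one region's activity distribution maps onto
another's — not merely whether the two are correlated.

The package provides:

- exact and numerical density transformations (`power_law_transform`,
  `exponential_tilt`, `integrate_mixed_flow`) on gridded densities, with
  closed-form Gaussian behavior verified to 1e-6;
- Gaussian KDE with robust Silverman bandwidths and exact log-sum-exp
  log-densities (`kde_model`, `kde_log_density`, `kde_to_grid`);
- density comparison metrics: squared 2-Wasserstein, total variation, L2
  (`wasserstein2_sq`, `total_variation`, `l2_distance`);
- the directed predictor and its estimator (`flow_fit`, with `coef`,
  `predict`, `summary`, `simulate`, `plot` methods);
- validation and significance machinery: hold-out and randomized
  cross-validation, circular-shift permutation testing,
  Benjamini–Hochberg and Bonferroni correction, and an all-pairs
  directional analysis (`holdout_validate`, `random_cv`,
  `circular_permutation_test`, `bh_fdr`, `bonferroni`,
  `pairwise_analysis`);
- forward-generative benchmarks for construct validation
  (`simulate_gaussian_diffusion`, `simulate_langevin`,
  `generate_pair_from_flow`, `run_density_recovery`,
  `run_series_recovery`);
- CSV ingestion of regional recordings, first-PC extraction from pixel
  stacks, and reproducible run reports (`load_recording`, `first_pc`,
  `run_report`), plus a thin command-line wrapper in
  `inst/cli/mixedflow.R`.

## Worked example

Simulate an autocorrelated source (a Langevin process with sinusoidal
drift), generate a coupled target with known coefficients plus 5%
observation noise, fit the directed predictor, and test its significance
against circular-shift surrogates:

```r
library(mixedflow)

x    <- simulate_langevin(duration = 30, seed = 42)
pair <- generate_pair_from_flow(x, flow_params(alpha = 0.05, beta = 0.5),
                                noise_sd = 0.05 * sd(x), seed = 43)

fit <- flow_fit(x, pair$target, labels = c("source", "target"))
fit
#> Mixed-flow fit: source -> target
#>   alpha (entropy)     = 0.05104
#>   beta  (expectation) = 0.5005
#>   training R^2 = 0.9989, MSE = 0.0002347, n = 3001

circular_permutation_test(x, pair$target, n_perm = 1000, seed = 44)
#> <permutation_result> empirical R^2 = 0.9989, 1000 surrogates, p = 0
#>   surrogate R^2: median 0.1850, max 0.9869
```

The fit recovers the generating coefficients (0.05, 0.5) to within about
2% and 0.1% respectively; the permutation p-value of 0 means no surrogate
out of 1000 reached the empirical R² once the temporal alignment between
source and target was destroyed. The full construct-validation experiment
wraps this end to end:

```r
run_series_recovery(seed = 1)
#> <recovery_report> series-space benchmark
#>   true  (alpha, beta) = (0.05, 0.5)
#>   fitted(alpha, beta) = (0.04957, 0.49941)
#>   relative errors: alpha 0.86%, beta 0.12%
#>   metrics: tv = 0.0003624, rmse = 0.0002918, r2 = 0.9989
```

Here `tv` is the total variation between the KDE value-distributions of
the ground-truth and reconstructed target trajectories and `rmse` their
root-mean-square difference.

For multi-region data, build or load a recording and run the full
directional screen:

```r
rec <- load_recording("recording.csv")   # time column + one column per region
res <- pairwise_analysis(rec, n_perm = 1000, q = 0.01, seed = 1)
run_report(res, "results/")              # matrices as CSV + JSON manifest
```

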