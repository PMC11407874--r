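# bactrack

Quantifies the surface motility of rod-shaped bacteria (e.g. *Bacillus
subtilis*) at expanding colony edges from time-lapse micrographs, and
provides a synthetic-data generator with known ground truth so every stage
of the measurement chain can be validated by parameter recovery.

The pipeline is: **segment** each frame (white top-hat enhancement → Otsu
threshold → watershed splitting → equivalent-ellipse measurement), **track**
cells across frames (nearest-neighbour linking within a gate), and
**analyse** the trajectories:

* time-averaged and ensemble mean squared displacement
  ⟨Δr²(t)⟩ with pair counts per lag;
* two-regime power-law fits ⟨Δr²(t)⟩ ∼ t^α — an early exponent α₁ (lags ≤
  t_c, default 3 s) and a late exponent α₂ (lags > t_c), plus a
  free-boundary fit that locates t_c itself;
* the large-displacement probability `p_large` = fraction of cells whose
  maximum displacement exceeds 3.5 body lengths, and the zero-displacement
  fraction of cells that never move beyond localization noise;
* per-cell exponent distributions whose spread (sd, IQR) measures dynamic
  heterogeneity.

The synthetic module simulates fractional Brownian motion cohorts (exact
Cholesky synthesis; anomalous exponent α = 2H), persistent random walks
(exact Ornstein–Uhlenbeck transition; Fürth MSD
4σ_v²P[t − P(1 − e^(−t/P))] with a ballistic→diffusive crossover near P),
immobile subpopulations, and renders trajectories as capsule-shaped cells
into noisy multi-page TIFF stacks.

## Worked example

Simulate a diffusive cohort (Hurst 0.5, so the true exponent is 1.0),
compute its ensemble MSD and fit the two regimes:

```r
library(bactrack)

set <- simulate_preset("nacl-late", seed = 3)   # 200 cells x 600 frames
ens <- ensemble_msd(as_tracks(set))
head(as.data.frame(ens), 3)
#>   lag_s  msd_um2 n_pairs
#> 1   0.5 1.003120  119800
#> 2   1.0 2.008827  119600
#> 3   1.5 3.017967  119400

fit_two_regime(ens, t_c = 3, lag_range = c(0.5, 30))
#> <two_regime_fit> alpha1 = 1.001 (R2 1.000, 6 lags) | alpha2 = 0.996 (R2 1.000, 54 lags) | t_c = 3 s

displacement_stats(as_tracks(set), body_length = 4, noise_floor = 0.1)
#> <displacement_stats> p_large = 0.990 (> 3.5 x 4 um) | zero_fraction = 0.000 (<= 0.1 um) | 200 tracks
```

The fitted exponents recover the simulated α = 2H = 1.0 on both sides of
the 3 s boundary, and essentially every cell of this fully motile cohort
displaces beyond 3.5 body lengths over the 300 s observation.

`run_pipeline()` chains simulate → render → segment → track → analyse under
one seed from a YAML/JSON config (see `load_run_config()`), and
`inst/scripts/bactrack.R` exposes the same stages as CLI subcommands
(`simulate`, `render`, `segment`, `track`, `analyze`, `run-all`,
`compare`). The methods vignette
(`vignettes/motility-analysis.Rmd`) documents the models, estimator
conventions and design choices.

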