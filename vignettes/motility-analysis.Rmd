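---
title: "Quantifying bacterial surface motility: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial surface motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactrack)
```

## The problem

At the expanding edge of a *Bacillus subtilis* colony, individual rod-shaped
cells move in a single layer that can be imaged by time-lapse microscopy.
Their motion is heterogeneous: some cells swim or slide actively, others are
effectively pinned. Two summary statistics capture this behaviour. First,
the ensemble mean squared displacement
$\langle \Delta r^2(t) \rangle \sim t^{\alpha}$ typically shows *two*
power-law regimes — an early super-diffusive regime
($1 < \alpha_1 \le 2$) crossing over at a few seconds to a late regime that
can be diffusive ($\alpha_2 \approx 1$) or sub-diffusive
($\alpha_2 < 1$) depending on growth conditions. Second, population-level
fractions — how many cells ever displace further than a few body lengths,
and how many never move beyond localization noise — quantify the split into
motile and immobile subpopulations. The spread of per-cell exponents
measures dynamic heterogeneity.

`bactrack` implements the full measurement chain — segmentation, tracking,
MSD analysis — together with a synthetic-data generator that produces
trajectories with *known* exponents, crossover times and immobile
fractions, so that every stage can be validated by parameter recovery
rather than by eye.

## Motility models

### Fractional Brownian motion

Each coordinate is an independent fractional Brownian motion with Hurst
index $H \in (0,1)$ and per-component MSD $\sigma^2 t^{2H}$
(`sigma_step` $= \sigma$, µm/s$^H$), so the 2-D ensemble MSD is
$2\sigma^2 t^{2H}$ and the anomalous exponent is $\alpha = 2H$ at *all*
lags. This makes fBm the natural calibration model for exponent recovery:
a cohort built with $H = 0.35$ must yield $\alpha = 0.7$, one with
$H = 0.70$ must yield $\alpha = 1.4$, and any estimator bias shows up
immediately.

Synthesis is exact: the increments form fractional Gaussian noise with
autocovariance
$\gamma(k) = \tfrac{\sigma^2 \Delta t^{2H}}{2}\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right)$,
and we draw them by Cholesky factorization of the Toeplitz covariance of
all `n_frames - 1` increments. This is $O(T^3)$ in the frame count and is
intended for desk-scale cohorts (up to a few thousand frames); it was
chosen over approximate spectral methods because exactness is what makes
the generator usable as a ground truth.

### Persistent random walk

The second model has exponentially decorrelating velocity: each component
follows a stationary Ornstein–Uhlenbeck process with relaxation time $P$
(`persistence_time`, s) and stationary standard deviation $\sigma_v$
(`speed_sd`, µm/s); positions integrate the velocity. The 2-D MSD is the
Fürth form
$$\langle \Delta r^2(t) \rangle \;=\; 4\sigma_v^2 P\left[t - P\left(1 - e^{-t/P}\right)\right],$$
ballistic ($2\sigma_v^2 t^2$, log–log slope 2) for $t \ll P$ and diffusive
($4\sigma_v^2 P\, t$, slope 1) for $t \gg P$. This is the model used to
test crossover recovery.

The discretization is *not* Euler: per frame we sample the exact joint
Gaussian of the velocity and the integrated displacement, with
$\mathrm{Var}(M) = \sigma_v^2(1-a^2)$,
$\mathrm{Cov}(M,N) = \sigma_v^2 P (1-a)^2$ and
$\mathrm{Var}(N) = 2\sigma_v^2 P\,[\Delta t - 2P(1-a) + \tfrac{P}{2}(1-a^2)]$
where $a = e^{-\Delta t/P}$, $M$ is the velocity innovation and $N$ the
displacement innovation. The closed-form MSD therefore holds in
expectation at *any* frame interval, which the test suite verifies at
every lag against Monte-Carlo standard errors.

### Immobile subpopulation and localization noise

`mix_immobile_fraction()` pins a seeded random subset of cells at their
initial position and re-applies i.i.d. Gaussian localization noise
(`loc_noise_sd`, µm, per component per frame). Localization noise is also
added to mobile cells; it is the only imaging imperfection represented at
the trajectory level.

### Boundaries

The `arena` parameter is optional. When it is given, positions are folded
back by reflection at the walls (reflection, unlike periodic wrapping,
keeps displacements physical at lags far below the wall-crossing time).
The default is `NULL` — an unbounded plane — because the analysis presets
are trajectory-level calibration cohorts and an unbounded domain keeps the
closed-form MSDs exact. Rendering, which needs a finite field of view,
uses in-field fixtures or the `pad_um` offset instead.

## Rendering

`render_frames()` draws each cell as a capsule — a rectangle of length
`cell_length − cell_width` with semicircular caps — at its ground-truth
position, blurs the frame with a Gaussian PSF and applies Gaussian or
Poisson noise at the configured bit depth. Orientation follows the
smoothed direction of motion by default (`along_velocity`, with a 3-frame
axial smoothing window on the doubled angle, since rods at a colony edge
align with their motion); `fixed` and `random_walk_angle` are available
for controlled fixtures.

Coordinates use the pixel-centre convention: the top-left pixel is (0, 0),
x runs along columns, y down rows, and a position $x$ µm maps to pixel
coordinate $x/\texttt{pixel\_size}$. Default calibration is
0.1 µm/px, 4 µm × 1 µm cells, and a 0.5 s frame interval. The pixel size
and cadence of any given microscope differ, so all three are configurable;
the defaults were chosen once so that a crossover near 3 s spans several
frames and a cell spans ~40 px — comfortably resolvable for the watershed.

## Segmentation

The per-frame chain is the classic one for bright rods on a dark
background:

1. **`enhance_contrast()`** — white top-hat with a disc structuring
   element (default diameter: the cell width in px plus a 2 px margin).
   The top-hat was chosen as the enhancement step because it removes any
   additive background exactly (a documented, testable property) while
   keeping features at the cell scale.
2. **`otsu_binarize()`** — Otsu's threshold on a 256-bin histogram of the
   range-normalized frame; invariant to positive affine intensity maps; a
   constant frame is an error, not an empty mask.
3. **`watershed_split()`** — components below `min_area` (default 25% of
   the expected single-cell pixel area) are removed, then the foreground
   is partitioned by watershed on the negated Euclidean distance
   transform with seeds separated by at least `min_seed_separation`
   (default 0.8 × cell length in px, tuned to split end-to-end contacts;
   laterally overlapping parallel rods are not separable by a distance
   transform and are out of scope).
4. **`measure_objects()`** — equivalent-ellipse measurement from the
   second central moments of each label's pixel coordinates, with axis
   lengths $4\sqrt{\lambda_i}$ and orientation in $(-\pi/2, \pi/2]$ from
   the +x axis. Note that a capsule's moment-equivalent major axis is
   slightly *longer* than its geometric length (≈ 4.39 µm for a
   4 µm × 1 µm capsule), because the rounded caps carry more area than
   the corners they replace; round-trip tests account for this.
   Border-touching objects are flagged and dropped by default — their
   shape and subsequent displacement are censored by the field edge.

These steps are built on EBImage's morphology, thresholding, distance
transform and watershed; the moment measurement is computed in-package so
that the axis-length convention is exactly the one stated above.

## Tracking

`link_successive()` implements follow-your-neighbour association:
candidate pairs within `gate_radius` (default 2 µm, half a cell length per
frame) are sorted by ascending centroid distance — ties broken
deterministically by frame-t then frame-t+1 index — and accepted greedily
one-to-one. Greedy matching was chosen over global assignment because it
matches the nearest-neighbour semantics, is deterministic and is accurate
at colony-edge densities where spacing far exceeds per-frame displacement;
the linker is a documented swap point if a crowded regime ever requires
optimal assignment. There is no gap closing and no merge/split handling
(cell division is negligible at these timescales). Tracks shorter than
`min_track_length` (default 2) are discarded but counted.

## Motility statistics

### MSD estimators

`msd_per_track()` is the time-averaged MSD. `ensemble_msd()` pools squared
displacements over all tracks, weighting each track by its pair count at
each lag — equivalently, the mean over every displacement pair in the
cohort. Pairs weighting (rather than equal per-track weighting) was chosen
as the default because it is the maximum-use estimator for cohorts with
unequal track lengths; both are available, and pooling conservation
(ensemble = pairs-weighted mean of per-track curves) is enforced by a
property test. Lags are limited to `max_lag_fraction = 0.25` of the track
length by default, the usual guard against the large variance of
time-averaged MSD estimates at lags comparable to the track duration.

### Two-regime fits

`fit_two_regime()` fits $\log_{10}$ MSD against $\log_{10}$ lag by OLS
separately for lags $\le t_c$ and $> t_c$, with $t_c = 3$ s by default and
configurable. No continuity is imposed at $t_c$: the two regimes are
reported as two independent slopes with their own prefactors and $R^2$.
Lags with non-positive MSD are excluded with a warning; fewer than three
usable lags in either regime is an error naming the regime.

### Free-boundary crossover

`fit_crossover()` scans candidate regime boundaries, resampling the curve
onto a log-spaced lag grid (default 10 lags per decade, snapped to
observed lags) and minimizing the summed OLS residual of the two lines.
Log spacing is the standard choice for MSD fitting — on a linear grid the
long lags dominate and drag the boundary upward.

Two caveats are worth stating plainly, both visible in the test suite's
analytic-curve fixtures. First, a smooth crossover has no sharp knee: for
the Fürth curve with $P = 3$ s evaluated over 0.25–25 s, the residual-
optimal boundary sits near 3.5 s at the default grid, i.e. somewhat
*above* the velocity relaxation time, and moves further up (towards the
asymptote-intersection time $2P$) as the grid densifies or the window
lengthens. Second, the discrete estimate can only take values on the
candidate grid, so its resolution is the grid spacing (~26% at 10 lags
per decade). The estimator is therefore a locator of the regime boundary
to within tens of percent, not a precision estimator of $P$; applications
needing $P$ itself should fit the Fürth form directly.

### Displacement statistics

`displacement_stats()` reduces each track to its maximum displacement
$d_i = \max_t |r(t) - r(0)|$ (relative to the first point — the "how far
did this cell ever get" reading; the all-pairs maximum is available via
`max_mode`). Then

* `p_large` is the fraction of tracks with $d_i >$ `factor` × body length
  (default 3.5), the probability that a cell displaces several body
  lengths — insensitive to localization noise and easy to communicate;
* `zero_fraction` is the fraction with $d_i \le$ `noise_floor`, the
  apparent-immobile fraction.

The noise floor deserves care. For a truly immobile cell observed over
$n$ frames, $d_i$ is the maximum of $n$ Rayleigh-distributed distances of
scale $\sqrt{2}\,\sigma_{\mathrm{loc}}$, so its typical value *grows* with
track length; a floor set at a small multiple of $\sigma_{\mathrm{loc}}$
misclassifies nearly every immobile cell once tracks are a few hundred
frames long. `noise_floor_for()` returns the closed-form 99% quantile
$\sigma_{\mathrm{loc}}\sqrt{2}\sqrt{-2\ln\left(1 - p^{1/n}\right)}$
(≈ 6.6 $\sigma_{\mathrm{loc}}$ at $n = 600$), which the pipeline uses as
its default floor whenever the localization noise level is known.

### Exponent distributions

`exponent_distribution()` applies the two-regime fit to every track's
time-averaged MSD and reports the per-track $\alpha_1, \alpha_2$ lists
with their standard deviation and IQR per regime. Time-averaged per-track
MSDs are used (each cell characterized by its own trajectory); tracks that
cannot support at least `min_lags_per_regime` positive lags per regime are
excluded and counted. Per-track exponent estimates are intrinsically noisy
(single-trajectory MSDs fluctuate), so the spreads should be compared
between cohorts analysed identically, not read as absolute heterogeneity.

## Presets: the study conditions

The named presets in `motility_preset()` fix the simulated study
conditions used throughout testing:

| preset | model | purpose |
|---|---|---|
| `nacl-early` | fBm, $H = 0.70$ | early-regime recovery target $\alpha_1 = 1.4$ |
| `control-early` | fBm, $H = 0.635$ | early-regime target $\alpha_1 = 1.27$ |
| `nacl-late` | fBm, $H = 0.50$ | late-regime diffusive target $\alpha_2 = 1.0$ |
| `control-late` | fBm, $H = 0.35$ | late-regime sub-diffusive target $\alpha_2 = 0.7$ |
| `crossover` | PRW, $P = 3$ s, $\sigma_v = 0.2$ µm/s | crossover recovery |
| `control` | fBm $H = 0.35$ + 50% immobile | paired-condition comparisons |
| `nacl` | fBm $H = 0.50$ + 10% immobile | paired-condition comparisons |

The fBm cohorts use 200 cells × 600 frames at 0.5 s; the PRW cohort 300 ×
400 at 0.25 s. `sigma_step` is 1 µm/s$^H$ throughout, which puts
per-frame steps near 0.7–0.8 µm (speeds of order 1.5 µm/s — realistic for
cells moving at an expanding colony edge). The paired-condition presets
add 0.05 µm localization noise — a typical centroid precision at
0.1 µm/px — so that immobile cells have finite, fittable MSDs, and their
immobile fractions (0.5 without added salt, 0.1 with) encode the
motile-subpopulation shift the comparison statistics are designed to
detect. These choices were made once, as the definition of the synthetic
study conditions, and the acceptance checks run against them unchanged.

## What the synthetic data does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
tunable anomalous exponents, a ballistic-to-diffusive crossover, an
immobile subpopulation, localization noise, and rod-shaped cells rendered
with PSF blur and shot noise at colony-edge-like density. It deliberately
omits cell growth and division, cell–cell mechanical interaction and
alignment, secreted-polymer fields, intensity inhomogeneity and
phase-contrast artifacts, and stage drift. Passing the recovery tests
therefore demonstrates that the estimators are unbiased and the pipeline
is faithful *given* the model assumptions; it does not certify
segmentation performance on crowded or low-contrast real micrographs,
which should be spot-checked per dataset.

## Numerical and degenerate-input conventions

* Same seed ⇒ bit-identical trajectory tables, image stacks and pipeline
  outputs; every stochastic stage takes or derives a seed.
* Constant frames are an error in `otsu_binarize()` (no threshold
  exists); empty masks yield empty label images, and empty label images
  yield empty observation tables — not errors.
* Zero-MSD lags are dropped from log–log fits with a warning; a cohort
  whose MSD is entirely zero (all cells pinned, no noise) skips the
  power-law fits in `run_pipeline()` but still reports displacement
  statistics.
* Linking tie-breaks are lexicographic by (distance, index, index), so
  results are independent of within-frame observation order except for
  exactly tied distances.
* The fBm Cholesky factorization is exact and limited in practice to a
  few thousand frames per track.

## Problem sizes

The test suite and the acceptance script run the presets at their stated
sizes (200 × 600 and 300 × 400 trajectories), Monte-Carlo oracle checks at
up to 10⁴ short tracks, and image-path checks on a 30-cell,
600 × 600 px, 12-frame high-SNR stack — sizes chosen so the full suite
completes in a few minutes on one core while keeping standard errors small
enough for ±0.1 exponent assertions.

## Known limitations

* The watershed cannot split laterally overlapping parallel rods; at true
  colony-edge packing the segmentation recall will degrade before the
  tracking does.
* Per-track exponent spreads conflate population heterogeneity with
  single-trajectory estimation noise; only like-for-like comparisons are
  meaningful.
* The free-boundary crossover estimator locates the regime boundary at
  grid resolution and with the upward bias discussed above.
* The linker is greedy nearest-neighbour with no gap closing: a missed
  detection splits a track in two rather than bridging it.
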