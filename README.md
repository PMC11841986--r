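# gridvar

Grid cells in medial entorhinal cortex fire on the vertices of a triangular
lattice and are organized into modules that share, approximately, one grid
spacing (λ) and one orientation (θ). `gridvar` asks how *approximately*:
it quantifies the small within-module heterogeneity of λ and θ in
simultaneously recorded populations, tests whether that heterogeneity is a
robust property of the cells rather than estimation noise, and measures its
functional consequence — that variability in grid properties breaks the
translational ambiguity of a single module's population code and allows
position within a local arena to be decoded from one module alone.

The package is written for systems neuroscientists working with open-field
grid-cell recordings (trajectory + spike times + module labels) or with
synthetic grid populations.

## What it computes

**Grid fitting.** Rate maps are built by binning the arena (3 cm bins by
default), normalizing spike counts by occupancy and applying mask-aware
Gaussian smoothing. The spatial autocorrelogram (SAC) is the Pearson
correlation of the map with itself at every 2-D lag; after masking the
central peak, the six inner peaks are located and the three axis peaks
(near 0°/60°/120°) give per-axis spacing λₖ (peak radius × bin size) and
orientation θₖ. The reported spacing is the arithmetic mean of the three
axes and the orientation the circular mean of (θₖ − 60°·k) on the
60°-periodic circle. Fits must satisfy hexagonal inclusion criteria
(adjacent axis angles within [30°, 90°]; axis-spacing ratios within
(0.5, 2)). The grid score is the standard annulus statistic
`min(r60, r120) − max(r30, r90, r150)` of SAC rotations.

**Within- vs between-cell variability.** The session is split into 30 s
temporal bins randomly assigned to two balanced halves; grid properties are
fit on each half; `Δθ_within(i) = d(θ_A(i), θ_B(i))` and
`Δλ_within(i) = |λ_A(i) − λ_B(i)|` measure a cell against itself, while a
random derangement pairs each cell with a different cell for
`Δθ_between(i,j) = d(θ_A(i), θ_B(j))` (orientation distances on the 60°
circle). Repeating over 100 shuffles, with cells rejected if more than 5%
of their shuffles produce poor grid fits, gives per-cell mean variabilities
and a one-sided paired Wilcoxon test of between > within. Robust
heterogeneity shows up as between-cell variability exceeding within-cell
variability for nearly all cells.

**Synthetic modules and decoding.** Ideal grid cells are sums of three
plane waves with wave vectors of magnitude `4π/(√3·λ)` at 60° separations:

    X(x) = Xmax · (2/3) · [ (1/3) Σⱼ cos(kⱼ(θ)·(x + φ)) + 1/2 ]

with λ ~ N(λ̂, σλ), θ ~ N(θ̂, σθ), phase φ uniform over the arena, and peak
rate Xmax ~ N(13, 8) Hz saturated into [2, 30] Hz. Poisson noisy maps
(counts with mean equal to the rate) feed a cross-validated linear template
decoder: templates are the mean of 9 of 10 noisy maps, the held-out map is
decoded at each position by the argmax of the summed product against the
templates, and the error is the Euclidean distance to the true position.
The generator also produces full synthetic recordings (smooth
Ornstein-Uhlenbeck foraging trajectory, inhomogeneous-Poisson spike trains
by thinning) so the whole fitting pipeline can be validated against known
ground truth.

## Worked example

```r
library(gridvar)

# a synthetic module of 5 cells, 40 min of foraging, known ground truth
rec <- simulate_session(grid_population_spec(n = 5), duration_s = 40 * 60,
                        seed = 7)
fit_session(rec)[, c("unit_id", "grid_score", "spacing", "orientation")]
#>   unit_id grid_score spacing orientation
#> 1 cell001       1.40    89.1        7.73
#> 2 cell002       1.41    87.2        6.68
#> 3 cell003       1.39    83.4        7.30
#> 4 cell004       1.47    88.6        4.65
#> 5 cell005       1.60    74.7        5.43

vr <- shuffle_analysis(rec, grid_config(n_shuffles = 20), seed = 8)
summarize_variability(vr)
#>   n_accepted mean_within_dtheta mean_between_dtheta mean_within_dlambda
#> 1          5               0.82                 1.8                 1.1
#>   mean_between_dlambda pct_between_gt_within_theta pct_between_gt_within_lambda
#> 1                  6.6                         100                          100
#>   p_theta p_lambda
#> 1    0.03     0.03
```

The fitted spacings (74.7–89.1 cm) recover the generator's λ ~ N(85, 5) cm.
Every cell shows more between- than within-cell variability for both
properties (`pct_* = 100`), i.e. the heterogeneity is reproducible across
random split halves of the same recording — the signature that
distinguishes true property differences from fitting noise. `tidy(vr)`
returns the per-cell table, `autoplot(vr)` the within/between scatter.

Decoding from a synthetic module:

```r
sw <- population_size_sweep(grid_population_spec(), ns = c(16, 256, 1024),
                            n_populations = 3, seed = 3)
sw$summary
#>   n_cells mean_error sd_error
#> 1      16       73.0     3.06
#> 2     256       33.5     3.19
#> 3    1024       15.2     3.67
```

With realistic variability (σλ = 5 cm, σθ = 1°) the error falls far below
chance (78.2 cm) as the population grows; with σ = 0 the curve stays near
70 cm regardless of population size (`autoplot(sw)` draws the curves).

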