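---
title: "Methods: quantifying within-module grid-property variability and its effect on decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying within-module grid-property variability and its effect on decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(gridvar)
```

This vignette documents the models, estimators and numerical choices behind
`gridvar`, in the spirit of a methods section: what is computed, under
which assumptions, which knobs matter, and where the design was genuinely
open.

## The measurement problem

A grid module is a set of simultaneously recorded cells whose firing
fields form triangular lattices with approximately equal spacing λ and
orientation θ. Measured λ and θ always scatter across cells; the question
is whether that scatter reflects real cell-to-cell differences or only the
noise of estimating lattice parameters from finite, noisy data. The
package's core statistic settles this with a split-half design: noise that
arises from estimation affects two halves of the *same* cell's recording
as much as it affects two *different* cells, so robust heterogeneity shows
up as between-cell differences exceeding within-cell differences.

## Rate maps and autocorrelograms

Positions are binned into square bins (`bin_size_cm`, default 3 cm, giving
50 × 50 bins for the 1.5 m arena — fine enough that the SAC peak radius of
a 65–100 cm module spans 20–35 lag bins). Each position sample contributes
its following inter-sample interval as dwell time to the bin containing
it; the last sample contributes the median interval, so summed occupancy
equals the recording duration exactly. A bin is *visited* when it holds at
least one sample's dwell; unvisited bins are `NA`, never 0 Hz.

Smoothing is mask-aware: the raw rate map (and the visited mask) are
convolved with a truncated Gaussian (`ratemap_smooth_sigma_bins`, default
1 bin) and the ratio is taken, so bins near the boundary or near holes in
coverage are not biased toward zero. The smoothing width for the raw maps
is a config default rather than a fixed constant; analyses that depend on
it should report sensitivity.

The SAC is the Pearson correlation of the map with itself at every integer
2-D lag, computed over bin pairs where both bins are visited. Lags with
fewer than `min_sac_overlap` (default 20) overlapping pairs are undefined:
correlations over a handful of pairs are noise. The implementation
computes the six masked cross-correlation sums with FFTs; the unit tests
verify it against a direct quadratic-time oracle. A map with no rate
variance yields a SAC explicitly flagged degenerate rather than silent
`NaN`s.

## Fitting spacing, orientation, grid score

The SAC centre peak is masked before peak detection. The mask radius
adapts to the module scale: the first minimum of the radially averaged SAC
profile, clamped to `[2 bins, 0.3 × half-width]`. Peaks are local maxima
(8-neighbour rule) of the σ = 1 smoothed SAC above `sac_peak_threshold`
(default correlation 0.1; the exact level matters little because
candidate peaks are then ranked by radius).

Peak locations are refined to sub-bin precision by a least-squares
paraboloid through the 3 × 3 neighbourhood (`refine_peaks = TRUE` by
default). With integer-bin peaks, a 3 cm grid quantizes the angle of a
~28-bin-radius peak in ~2° steps, and the resulting spacing/orientation
error depends on the lattice phase; with refinement the worst-case
recovery error on noiseless ideal maps across a 5 × 5 sweep of
(λ ∈ [50, 100] cm, θ ∈ [0°, 12°]) and several phases is below 0.4 cm and
0.1°. The purely discrete procedure remains available (`refine = FALSE`).

Of the six inner peaks, angles are reduced modulo 180° into [−15°, 165°)
and one peak is kept per nominal axis (0°, 60°, 120°; nearest angle, ties
to the larger SAC value). Spacing is the mean of the three peak radii
times the bin size — radii are measured in lag bins of the rate-map grid,
so no additional scale factor applies. Orientation is the circular mean of
(θₖ − 60°·k) computed on the 60°-periodic circle (angles multiplied by 6,
averaged as unit vectors, divided by 6), because arithmetic means are
wrong near the 0°/60° wrap. Inclusion requires adjacent axis angles
between 30° and 90° and pairwise spacing ratios strictly inside (0.5, 2);
the first failing rule is reported (`angle_lt_30`, `angle_gt_90`,
`spacing_ratio`). The adjacency reading is deliberate: the three axis
peaks of a perfect grid are 60° apart consecutively but 120° apart
end-to-end, so an all-pairs reading would reject every ideal lattice.

The grid score correlates the SAC annulus (inner radius at the mask, outer
radius 1.25 × the outermost inner peak, clamped to the SAC; 0.7 ×
half-width when no peaks exist, so unstructured maps still score) with
itself rotated 30°–150°: `min(r60, r120) − max(r30, r90, r150)`. Ideal
lattices score well above 1; spatial noise scores near 0.

A control estimator, `spacing_from_ratemap()`, measures spacing from
firing-field centres near the arena centre instead of the SAC (fields cut
by the walls bias the SAC estimate upward). Among the six most central
fields it uses the most equilateral triple (smallest relative spread of
pairwise distances). A literal "three nearest to the centre" rule is
unstable: on a triangular lattice the three lattice points nearest an
arbitrary point can be nearly collinear, which flips the pairwise mean
between λ and ≈1.24 λ as the phase shifts, while the most equilateral
central triple is a stable lattice triangle (translation changes the
estimate by well under 2 cm).

## The split-half resampling design

Each shuffle partitions time into consecutive `split_bin_seconds` bins
(default 30 s; the final partial bin, and if necessary the last complete
bin, are dropped to keep the count even) and assigns exactly half the bins
to each block at random. The same split is used for every cell of the
session — one behavioural timeline. Dwell times are computed once on the
full trajectory and carried with the samples, so the two halves conserve
occupancy exactly and no inter-bin gap is ever counted as dwell.

Per shuffle, a cell is *poor* if either half fails the inclusion criteria;
across `n_shuffles` (default 100), cells poor on ≥
`reliability_max_poor_frac` (default 5%, strict) of shuffles are rejected.
This reliability criterion is deliberately conservative: unreliable cells
would inflate the variability estimate.

Differences are magnitudes: `|λ_A − λ_B|`, and orientation distances on
the 60°-periodic circle mapped to [0°, 30°]. Signed differences average
toward zero over shuffles and would carry no information about variability
magnitude. Between-cell partners are drawn per shuffle as a random
derangement of the surviving cells — sampling without replacement, with
self-pairs excluded since they would contaminate the between-cell
statistic with within-cell values. Per-cell means are taken over the
shuffles in which the cell (and, for between, its partner) survived.
Summaries report population means, the percentage of cells with between >
within, one-sided paired Wilcoxon signed-rank tests, and optionally the
regression of within-cell variability on grid score.

### What the null calibration can and cannot show

For a homogeneous synthetic module (σ = 0) the between > within fraction
should be near 50%. It is near, but with very long, clean recordings not
exactly: the SAC spacing estimator carries a small per-cell systematic
bias (~0.2 cm) that depends on the cell's lattice *phase*, because the
arena truncates each cell's field lattice differently. That bias is
common to both halves of the same cell — within-cell differences cancel
it — but independent across cells, so it adds ~0.1 cm to between-cell
differences even when true variability is zero. At 130 minutes of Poisson
spiking the within-cell noise is only ~0.5 cm, so a 30-cell binomial test
can resolve this bias (observed 22/30 cells with between > within under
the null, p ≈ 0.02). The effect is two orders of magnitude smaller than
the between-minus-within excess produced by realistic heterogeneity
(σλ = 5 cm gives ≈ 5 cm of excess and >90% of cells), and at real-data
noise levels (within-cell means ~1.9 cm) it is invisible; but exact 50%
calibration should not be expected from very long, very clean sessions.

## The synthetic generator

`sample_population()` draws λ ~ N(λ̂, σλ) (non-positive draws redrawn),
θ ~ N(θ̂, σθ), phases uniform over the arena, and peak rates
Xmax ~ N(13, 8) Hz *saturated* into [2, 30] (values outside set to the
bounds, leaving point masses there). Defaults (λ̂ = 85 cm, θ̂ = 6°,
σλ = 5 cm, σθ = 1°, 1.5 m arena) are the module conditions to which the
analysis is calibrated: the σ values equal the mean between-cell minus
mean within-cell variability measured in the reference module, i.e. the
variability not attributable to noise.

Ideal rate maps sum three plane waves whose wave vectors have magnitude
`k = 4π/(√3·λ)` and directions θ + 30°, θ + 90°, θ + 150°, placing the
lattice axes at θ, θ + 60°, θ + 120° with nearest-peak distance exactly
λ. The magnitude convention is pinned by a closure property tested in the
suite: fitting the SAC of an ideal map must recover the generator's λ to
within 2 cm and θ to within 1° across the parameter sweep. Printed
variants of this construction that fail λ-recovery (e.g. reading the
constant as 4π/(3λ) with √2-length direction vectors, which inflates the
effective spacing by √(3/2) ≈ 1.22) are thereby excluded.

Noisy maps draw each bin independently from Poisson with mean equal to
the ideal rate (unit effective dwell; a config multiplier exposes other
dwell). Trajectories are Ornstein-Uhlenbeck velocity processes (τ =
0.7 s, Rayleigh stationary speed with mean 15 cm/s, dt = 0.02 s) folded
into the arena by reflection; their only contract is near-uniform
coverage (occupancy CV across visited bins < 1 at 130 min). Spike trains
thin a homogeneous Poisson process of rate Xmax by the acceptance
probability X(x(t))/Xmax.

What the generator does *not* emulate: theta-rhythmic and bursty spiking,
conjunctive head-direction tuning, firing-rate drift, grid shear or
ellipticity, and correlated noise across cells. Passing tests on synthetic
sessions therefore validate the estimators and the resampling logic, not
the behaviour of the pipeline under every pathology of real recordings.

## Linear template decoding

For each cell, 10 Poisson maps are drawn; each fold averages 9 into a
template and decodes the held-out map: position x is assigned the
candidate y maximizing Σᵢ X̃ᵢ(x)·X̂ᵢ(y), and the error is ‖x − ŷ‖. Errors
are averaged over all arena bins, the 10 folds, and (default) 25
independently sampled populations. The decoding grid matches the rate-map
resolution (50 × 50; the measured error is insensitive to resolution
between 25 and 50 bins per side). Argmax ties are broken deterministically
by the first index; with Poisson noise they have measure zero, but note
that reordering cells permutes floating-point summation and can flip
near-ties, so per-position errors are reproducible only up to such ties.
Chance error — decoding with templates carrying no spatial information —
equals the mean distance between two uniform points in the square,
`L(2 + √2 + 5·asinh 1)/15 ≈ 0.5214 L` (78.2 cm for L = 150 cm), which the
decoder reproduces when templates are spatially shuffled.

With module-level variability (σλ = 5 cm, σθ = 1°) the error falls with
population size to ~13 cm at N = 1024 (seed-to-seed SD across populations
~5 cm); with σ = 0 it stays near 70 cm, flat in N — single-module position
information comes from the heterogeneity, not the cell count. The ~13 cm
figure is somewhat below the ~20 cm scale reported for this experiment
elsewhere; the gap is consistent with the wave-vector convention noted
above (an effective spacing of ~104 cm rather than 85 cm reproduces
~20–23 cm), and the package deliberately keeps the calibrated convention,
treating lower error as the one-sided reading of the claim.

Two-module experiments concatenate a second population with
λ̂₂ = √2·λ̂₁ (consecutive modules) or λ̂₂ = 2·λ̂₁ (modules two steps
apart), with a configurable orientation offset (default 15°; the offset
between real modules is not standardized). Consecutive fixed-property
modules decode to a few cm — the classic multi-scale code; in the
integer-ratio case the larger module's lattice nests inside the smaller
one's, residual ambiguity persists with fixed properties, and
heterogeneity again lowers the error. Decoding of recorded (or simulated)
sessions follows the same argmax rule on per-cell maps from 10 contiguous
temporal bins (5 train / 5 test, max-normalized per cell, visited bins
only).

## Reproducibility and problem sizes

All stochastic stages derive their seeds deterministically from one
integer (`derive_seed()` in the source: a fixed affine hash of the stage
key and index), so any stage can be re-run in isolation and a fixed seed
makes all saved CSV values bit-reproducible. The test suite exercises the
full study conditions where they are cheap (130-minute, 30-cell sessions
with 100 shuffles; 1024-cell decoding with 25 populations) and reduced
sizes elsewhere (e.g. the fixed-vs-variable control at N ∈ {16, 256} with
8 populations, and two-module contrasts at N = 256 with 2 populations),
chosen as the smallest problems on which the contrasts of interest are
stable across seeds.

## Limitations

The estimators inherit the finite-arena biases discussed above (SAC
spacing biased slightly upward by wall-truncated fields; phase-dependent
systematic components of order 0.2 cm). The decoder is linear and assumes
independent Poisson noise; correlated variability would change both the
attainable error and the benefit of heterogeneity. Orientation is treated
as 60°-periodic throughout, which discards grid shear; per-axis outputs
(`axis*_spacing`, `axis*_orientation`) are provided so users can study
axes independently.
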