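---
title: "Quantifying gastruloid morphogenesis: models and methods"
author: "gastromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gastruloid morphogenesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastromorph)
```

# Scope

Gastruloids are three-dimensional aggregates of embryonic stem cells
that break symmetry, elongate an anteroposterior (AP) body axis, and
pattern marker expression (BRA/SOX2 posteriorly, FOXC1 anteriorly)
along it. Experiments that embed gastruloids in hydrogels of controlled
stiffness ask quantitative questions of microscopy data: how long and
how straight is the body axis, where do expression boundaries sit along
it, what fraction of organoids forms a unique posterior pole, how dense
are dividing cells, how motile are single cells inside the tissue, and
how fast does the whole organoid grow or drift.

`gastromorph` implements that measurement stack end to end, together
with a synthetic-scene generator that produces every input with known
ground truth. All quantities are physical from the moment of loading:
micrometres and minutes, with calibration always supplied by the caller
rather than read from image metadata.

This vignette explains the models and algorithms, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic benchmarks do and do not demonstrate about real data.

# Organoid masks and the sub-pixel contour

A mask (`OrganoidMask`) is a single 4-connected foreground component
with all holes filled; holes are filled unconditionally because the
profile binning below requires a simply connected region.
`segmentOrganoid()` produces masks by Gaussian smoothing (sigma 2 px),
a global threshold, retention of the largest component, and optional
closing. Otsu is the default threshold; the maximum-entropy method is
reserved for the mitotic-density analysis, where it is part of the
assay definition. Both thresholds are computed on a 256-bin histogram
spanning the observed intensity range, which makes them exactly
covariant with affine intensity shifts — adding a constant to an image
cannot change the mask.

Wherever a perimeter enters a formula the package uses a sub-pixel
contour: marching squares (`contourLines`) at level 0.5 on a Gaussian-
smoothed (sigma 2 px) copy of the binary mask. Pixel-edge perimeters
overestimate smooth boundaries by roughly 10%, and at smaller smoothing
the residual staircase ripple is orientation dependent at the 0.1–0.7%
level, which an area–perimeter compound like circularity amplifies
several-fold. At sigma 2 the measured elongation index of a rasterized
disk of radius 100 px is 0.0015, and rotating a capsule changes its
elongation index by well under 1%. The cost is a boundary displacement
of order `sigma^2 * curvature / 2` — about 0.04 px for a 50 µm cap
radius at 1 µm/px — which is negligible for organoid-scale shapes.

# The body axis: medial axis with tangent extension

The organoid length `L` is the arc length of the medial axis extended
to the organoid extremities. The implementation:

1. **Skeletonize** the mask by Zhang–Suen thinning (no installed R
   package provides binary thinning, so it is implemented here,
   vectorised over whole-image shifts).
2. **Prune to the body axis**: build the 8-connected skeleton graph
   with Euclidean edge weights and take the longest geodesic between
   skeleton endpoints; ties break on the lexicographically smallest
   endpoint pixel. An unbranched body axis is the longest path; short
   side branches are ignored automatically.
3. **Re-centre on the distance-transform ridge.** Discrete skeletons
   carry a lateral staircase bias of up to a few pixels on curved
   shapes. Across the true axis the distance map is tent-shaped, so the
   lateral offset of the ridge at a point `p` with unit normal `n` is
   exactly `(dm(p + w n) − dm(p − w n)) / 2`; three such correction
   passes (window `w` = 2 px, moving-average smoothing window 5 points
   in between) place the path on the ridge to sub-pixel accuracy.
4. **Prune terminal spurs.** Thinning grows short branches into rounded
   ends. After re-centring, genuine axis points sit on the local-width
   plateau of the distance map while spur points descend from it toward
   the boundary, so each end is trimmed while its distance-map value
   lies below the terminal plateau minus a slack of
   `max(1.5 px, 5%)`; a spur cannot outrun its terminal inscribed
   disk, so the trimmed arc is capped at 1.2 plateau radii.
5. **Extend with straight tangent rays.** The tangent at each end is
   the analytic end-slope of a quadratic fitted in the local secant
   frame of the last `tangent_k` points (default 40, capped at a third
   of the path). Short windows are corrupted by the pixel-scale zigzag
   of thinned paths — at 10 points the end tangent is wrong by up to
   14 degrees on benchmark capsules, versus under 1 degree at 40 — and
   the quadratic term removes the curvature bias a straight-line fit
   would introduce. Each ray is intersected with the sub-pixel contour;
   the two intersection points are the axis extremities.

Near-circular masks collapse to degenerate skeletons; these fall back
to a short segment through the centroid along the principal axis, so a
disk still reports `L` close to its diameter.

**Accuracy envelope** (rasterized capsules, sweep radius 50 µm,
centerline 200 µm, 1 µm/px): length error stays below 0.5% for
centerline turning angles up to 2.5 rad; straightness error is below
1% of the analytic chord/arc value for turning angles up to about
1.3 rad and grows to +0.03–0.04 absolute toward the self-contact limit,
where the straight-ray extension convention itself becomes
ill-conditioned. The package's property tests therefore sample
curvatures up to 1.3 rad of total turning for straightness recovery and
up to 0.8 π for length recovery.

# Shape descriptors

* **Straightness** `S = chord / arc` of the extended axis: 1 for a
  straight organoid, smaller when bent. The opposite convention
  (arc/chord, ≥ 1) is available via
  `straightness(x, orientation = "arc-over-chord")`; the chord/arc
  orientation is the default because only it makes "straightness
  approaches 1" describe a non-deforming organoid.
* **Elongation index** `EI = 1 − 4 π A / P²`, the complement of
  circularity, computed from the contour polygon's area and perimeter:
  0 for a disk (≤ 0.02 at ≥ 100 px radius after discretisation),
  0.314 for a capsule whose centerline is four cap radii, invariant to
  rotation and scaling within 2%.
* **Aspect ratio**: square root of the eigenvalue ratio of the
  foreground's second-moment matrix (the inertia-equivalent ellipse),
  with the single-pixel moment `px²/12` added to keep thin shapes
  non-degenerate.

# AP intensity profiles

Profile extraction follows the contour-cut construction: the contour is
cut at the two axis extremities, each half is resampled to 101
arc-length-equidistant points, and section `i` is the quadrilateral
joining points `i` and `i + 1` across the two sides. Pixels are
assigned to the section containing their centre; the assignment tests
every candidate section so that it is independent of section order and
exactly symmetric under mirroring. Pixels claimed by no section
(discretisation slivers) or by several (centres exactly on a shared
edge) go to the nearest section centroid. Sections at very thin or
blunt tips can be smaller than a pixel; their profile values are
imputed as the mean of the nearest non-empty neighbours and flagged in
the output (`imputed_bins`), which in practice affects only the flat
outermost bins.

The axial position of each section is the arc-length coordinate of its
centroid projected onto the medial axis, divided by `L` — for a
rectangle this reduces exactly to bin centres at `(i − 0.5)/100`.
Profiles live in an `APProfileSet`, a `SummarizedExperiment` with one
column per organoid and assays `raw`, `position` and (after
normalization) `normalized`, so standard Bioconductor tooling applies.

**Cohort normalization.** Because fixation differs between embedded and
free-floating samples, profiles are compared by shape: for each
experiment (and channel) the cohort-average profile is computed
bin-wise, the anchors are the means of its lowest and highest decile of
bins (10 of 100), and every profile is rescaled as
`(raw − low) / (high − low)`. The decile-mean reading of "the 10%
lowest and highest values" is chosen over single percentiles for
robustness, and the grouping is per experiment; both are configurable
(`by`, `decile`). The arithmetic keeps the anchor sums unscaled and
divides once at the end, so affine intensity transforms of a cohort
with exactly representable inputs (integer camera counts) produce
bit-identical normalized output — a property the test suite asserts
with `identical()`.

**Boundary calling.** The boundary position of a marker is the relative
axial position where the profile crosses the half-maximum
(`(min + max)/2`) of its values inside a search window, linearly
interpolated between bins; with several crossings the one nearest the
window's steepest gradient wins. Default windows are `[0.5, 1]` for
rising (posterior) markers and `[0, 0.5]` for falling (anterior) ones;
the benchmark cohort uses the full axis because its midpoints are drawn
from `U(0.2, 0.8)`. On 50 generator organoids with 10% multiplicative
noise the median absolute boundary error is about 0.005, well inside
the 0.02 target.

# Pole calling and bootstrap proportions

Published pole counts are visual scores; `callPoles()` replaces them
with a reproducible criterion: threshold the normalized profile at 0.5
and count maximal runs of at least 10 consecutive supra-threshold bins;
each run is a pole with its run-centre position. "Unique pole" means
exactly one run. The benchmark cohort calls poles on the generator's
raw profiles, which are produced on the normalized scale by
construction (baseline 0.05, amplitude 1); cohort normalization is
deliberately not applied across scenes of different pole multiplicity,
since anchors derived from a mixed cohort-average profile rescale
single-pole peaks beyond the guarded `[−0.5, 1.5]` range. Accuracy on a
60-scene cohort with 0/1/2 poles at 10% noise is 100%, against a 95%
requirement.

`bootstrapProportion()` reports the fraction with a nonparametric
bootstrap: `B = 1000` resamples by default, standard error of the
resampled proportions, a percentile 95% interval, and a mandatory seed.
At `n = 20`, `k = 15`, `B = 10000` the bootstrap SE reproduces the
analytic `sqrt(p(1 − p)/n)` within 0.5%.

# Mitotic density

The dividing-cell density assay is implemented exactly as defined:
Gaussian filter with sigma 5 px, maximum-entropy (Kapur) threshold of
the in-mask intensity histogram (256 bins over the observed range —
the 8-bit histogram convention), Euclidean distance transform and
watershed (tolerance 1, neighbourhood 5 px) to split touching objects,
and a count of objects of at least 10 px (`min_area_px`, configurable).
The Kapur criterion maximises the summed Shannon entropies of the
background and foreground class distributions; ties — which genuinely
occur, e.g. for symmetric spike histograms — resolve to the lowest
level within a 1e-10 float tolerance, and the implementation is tested
for exact agreement with an exhaustive entropy search on random
histograms.

The sigma 5 filter imposes a physical resolution limit: two nuclei
whose centres are closer than about twice the combined Gaussian width
(`2 sqrt(sigma_spot² + 25)` ≈ 12 px for 3 px spots) merge into a blob
whose level sets have no waist, and no watershed can split them.
Because the low-lying maximum-entropy threshold fattens the blob
further, splitting in practice requires about 18 px of separation under
these settings; the constructed touching-pair benchmark uses 20 px,
which still overlaps by less than one thresholded spot radius
(about 12 px).

# Time-lapse motion and radial growth

`timelapseMotion()` reduces a mask time series to the centroid track,
the cumulative centroid displacement, and the effective radius
`r(t) = sqrt(A(t)/π)`; the radial growth rate is the ordinary
least-squares slope of `r` against time. With 25 frames at 30 min
spacing and smooth ±1 px boundary jitter, a generated growth rate of
0.015 µm/min (the regime of interest for soft-gel embedding) is
recovered within 0.2%.

# Single-cell track statistics

Tracks are `(track_id, t, x, y, z)` tables in minutes and micrometres,
loaded from TrackMate-style CSV exports with caller-supplied
calibration and strictly increasing timestamps per track. The analysis
set keeps tracks of 10–25 time points, both bounds inclusive.

Per track: mean speed (summed 3-D step lengths over duration),
confinement ratio (net displacement over path length), and mean
directional change rate (mean unsigned angle between consecutive
steps per unit time; zero-length steps leave the angle undefined and
are skipped and counted). The MSD is time-averaged over all ordered
pairs at each lag and fitted as
`MSD(τ) = 2 · dims · D · τ^α` by least squares in log–log space over
lags up to 25% of the track duration, where long-lag estimates are
high-variance. Statistics default to 3-D (`dims = 3`), matching the
anisotropic light-sheet voxel calibration converted to micrometres at
load; `dims = 2` projects to xy. The ensemble MSD is the mean of
per-track MSD curves at shared lags, fitted the same way.

Two estimator properties matter for interpretation. First, the log-log
intercept sits at `log(2 · dims · D)` extrapolated to `τ = 1 min` from
lags of 20–120 min, so a small error `δα` in the exponent inflates `D`
by roughly `exp(4.3 δα)`; single-cohort `D` estimates at 50 tracks of
25 points scatter by ±10–15% even when `α` is within ±0.05. The
parameter-recovery benchmarks therefore report the median over three
independent cohorts. Second, isotropic localization noise adds a
constant `2 · dims · σ_loc²` to every time-averaged MSD value; at the
generator's stress-test default of 0.3 µm this offset is 45% of the
first-lag MSD for `D = 0.01` µm²/min sampled every 20 min, which under
an offset-free power-law fit necessarily depresses `α` to about 0.83
and inflates `D` — an estimator property, not a bug. Recovery
benchmarks consequently simulate the generative model itself
(localization noise 0), while the noise default remains available for
stress testing.

# The synthetic-scene generator

Every stage is tested against scenes with known truth, generated inside
`withr::with_seed` so identical parameters and seed are bit-identical
and global RNG state is never touched:

* **Masks**: capsules (discs swept along constant-curvature arcs) with
  closed-form axis length `a + 2r`, straightness, area and perimeter;
  optional smooth radial boundary jitter (6 Fourier modes, ±1 px
  amplitude). Noise defaults to off so the analytic oracles apply
  exactly; benchmarks that specify jitter request it explicitly.
* **Marker images**: each foreground pixel painted with a sum of
  logistic axial components evaluated at its arc-length coordinate on
  the medial axis, times 10% multiplicative Gaussian noise; truth
  records midpoints (= boundary positions) and implied pole count.
* **Nuclei planes**: Gaussian spots (sigma 3 px) at uniform in-mask
  positions with a minimum separation, over a noisy background.
* **Tracks**: Brownian (Gaussian steps of variance `2 D dt` per axis),
  ballistic (constant random direction), or confined
  (Ornstein–Uhlenbeck with stationary RMS radius equal to the
  requested confinement radius), all started at the origin, with
  optional localization noise (default 0.3 µm).
* **Time lapses**: re-rasterized disks with linear radius growth,
  per-frame centroid drift and optional angular boundary jitter.

What the generator does **not** emulate: optical point-spread
functions, shot noise and camera gain, intensity texture within the
tissue, 3-D shape (all masks are 2-D silhouettes), contact between
neighbouring organoids, and the multipolar morphologies seen in
remodellable matrices. Passing the benchmarks therefore demonstrates
the correctness and calibration of the measurement algorithms on
idealised geometry with realistic noise amplitudes — not robustness to
every imaging artefact of real microscopy, which should be assessed on
real data with the same quality flags the package emits
(border-touching masks, imputed bins, degenerate fits, skipped angles).

# Numerical choices and degenerate inputs

* Pixel convention: matrices are `(row = y, col = x)`, pixel centres at
  `(index − 1) × pixel size`; polygons and polylines are `(x, y)` in
  micrometres, counter-clockwise, closed.
* Threshold ties: lowest qualifying level (1e-10 relative tolerance).
* Skeleton-path ties: lexicographically smallest endpoint pixel.
* Zero-length steps in tracks: angle skipped and counted; stationary
  tracks flag `degenerate_fit` and report `MSD ≡ 0`.
* Empty profile bins: neighbour-mean imputation with flags.
* Percentile CI bounds are clamped to bracket the point estimate.
* Every stochastic routine takes an explicit seed; the pipeline runner
  stamps outputs with the package version, an order-independent config
  hash, and the seed.

Benchmark problem sizes were chosen to exercise each method at
realistic organoid scale while keeping the whole suite in the
low minutes: morphometry oracles at 1 µm/px (about 300 × 100 px
masks), profile/pole cohorts at 2 µm/px, 50 organoids for boundary
recovery, 60 scenes for pole classification, 3 × 50 tracks of 25
points for diffusion recovery, and 25-frame time lapses.

# Known limitations

* The medial axis is 2-D; strongly out-of-plane bent organoids are
  foreshortened in projection.
* Straightness accuracy degrades (systematically toward straighter)
  beyond about 1.3 rad of total axis turning, as the straight tangent
  extension becomes ill-conditioned near self-contact.
* The pole criterion operates on 1-D profiles; a pole that is narrow
  along the axis but bright off-axis may be missed relative to 2-D
  scoring.
* Nuclei closer than the watershed resolution limit (about 18 px under
  the assay's sigma 5 filter) are undercounted by construction.
* The TrackMate reader handles the single-header CSV dialect only, not
  TrackMate XML model files.
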