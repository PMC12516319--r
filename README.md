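# gastromorph

Quantitative image analysis for elongating stem-cell organoids
(gastruloids), for developmental-biology labs that measure
morphogenesis under controlled mechanical environments such as
hydrogel embedding. From calibrated microscopy images and single-cell
track tables, the package measures:

* **Morphometry** — the body-axis length *L* (arc length of the medial
  axis, tangent-extended to the organoid extremities), the
  straightness ratio *S* = chord/arc (1 for a straight organoid), the
  elongation index *EI* = 1 − 4πA/P² (0 for a disk), and the aspect
  ratio of the inertia-equivalent ellipse.
* **AP expression profiles** — 100-bin intensity profiles along the
  anteroposterior axis from the contour-cut construction (contour cut
  at the axis extremities, 101 equidistant points per side, mean
  intensity per quadrilateral section), per-experiment decile
  normalization, and half-maximum boundary positions *x_b* on the
  relative axis.
* **Pole formation** — a reproducible BRA/SOX2 pole criterion
  (supra-threshold runs of bins) and bootstrap proportion estimates
  with percentile confidence intervals.
* **Mitotic density** — dividing-cell counts from mitosis-marker
  planes via Gaussian(σ=5) filtering, maximum-entropy (Kapur)
  thresholding and watershed splitting, as counts per µm² of slice.
* **Cell motility** — per-track mean speed, confinement ratio,
  directional change rate, and the time-averaged mean squared
  displacement fitted as MSD(τ) = 2·d·D·τ^α (diffusion coefficient
  *D*, exponent *α*); plus organoid-scale centroid trajectories and
  radial growth rates from mask time lapses.
* **Synthetic scenes** — deterministic generators for all of the
  above with closed-form ground truth, used throughout the test
  suite.

Everything is unit-true (µm, minutes) from load time; calibration is
always supplied by the caller, never guessed from TIFF tags. Central
data structures are Bioconductor S4 classes; profile sets extend
`SummarizedExperiment`.

## Worked example

Generate a gently bent synthetic organoid (200 µm centerline, 50 µm cap
radius), measure its shape, and extract a BRA-like posterior profile:

```r
library(gastromorph)
library(SummarizedExperiment)

scene <- makeOrganoidMask(centerline_length_um = 200, cap_radius_um = 50,
                          curvature = 0.004, pixel_size_um = 1, seed = 11)
scene$mask
#> OrganoidMask: 185 x 289 px at 1 um/px | area 27849.0 um^2, perimeter 714.2 um

axis <- medialAxis(scene$mask)
morphometry(scene$mask, organoid_id = "g1")
#>   organoid_id length_um straightness elongation_index aspect_ratio area_um2 perimeter_um
#> 1          g1  299.4534    0.9623541        0.3143052     2.704638    27849     714.2369
```

The analytic truth for this shape is *L* = 300 µm (measured 299.45,
−0.2%) and *S* = 0.9561 (chord/arc of the true extended axis; measured
0.9624); *EI* is 0.3137 for the straight capsule of the same
proportions.

```r
binning <- makeBins(splitContour(scene$mask, axis), scene$mask, axis)
marker <- makeMarkerImage(scene$mask, axis,
                          list(list(midpoint = 0.6, steepness = 20)),
                          noise_sd = 0.1, seed = 12)
prof <- extractProfile(marker$image, binning, organoid_id = "g1",
                       channel = "BRA")
boundaryPosition(assay(prof, "raw")[, 1], assay(prof, "position")[, 1],
                 direction = "rising", window = c(0, 1))
#> [1] 0.6002574
```

The marker was painted with its half-maximum at 0.6 of the axis; the
pipeline recovers 0.600 despite 10% multiplicative noise. Pole calling
and a pole-formation proportion with bootstrap error bars:

```r
callPoles(assay(prof, "raw")[, 1], assay(prof, "position")[, 1],
          organoid_id = "g1")
#> PoleCall [g1]: 1 pole(s) at x = 0.832

bootstrapProportion(c(rep(1, 15), rep(0, 5)), B = 1000, seed = 7)
#> ProportionEstimate: p = 0.750 (n = 20), bootstrap se = 0.0948, 95% CI [0.550, 0.901], B = 1000
```

(The analytic binomial SE at n = 20, p = 0.75 is 0.0968.)

Full runs are orchestrated from a single YAML/list configuration with
provenance-stamped CSV outputs — see `?runPipeline` — and a thin
command-line wrapper lives at `inst/scripts/gastromorph.R`. The methods,
parameter choices and accuracy envelopes are documented in the vignette
(`vignettes/gastromorph-methods.Rmd`).

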