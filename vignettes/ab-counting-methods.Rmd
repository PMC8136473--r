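---
title: "Counting asbestos bodies in 3D micro-CT volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting asbestos bodies in 3D micro-CT volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abct)
```

## The problem

Asbestos bodies (AB) are asbestos fibres that acquired an iron-protein
coating during their residence in lung tissue. Their number per gram of
dry lung is the standard, most accessible marker of past asbestos
exposure. Conventional counting examines tissue digests or thin
histological sections under a microscope; it is slow, reader-dependent,
and — because a thin section samples a 3D population of elongated
objects — requires stereological approximations. X-ray micro-tomography
images the bodies directly in three dimensions inside bulk tissue, so
the count is exact and the morphometry of every body falls out of the
same computation.

`abct` implements the computational side of that approach: volume I/O
and chunking, grey-level segmentation, 3D connected-component labelling,
shape-descriptor filtering, fibre morphometry, and the stereological
conversion of a count per embedded-tissue volume into a burden per gram
of dry lung. Because public micro-CT volumes of AB-laden tissue are not
available, the package also ships a synthetic phantom generator with
exact per-fibre ground truth, so every stage is testable end to end.

## The detection pipeline

A reconstructed volume is a 3D grey-level field in which brighter means
denser. The pipeline is the classical particle-analysis cascade, run in
full 3D (never on projections, which fuse overlapping bodies):

1. **Segmentation** — a voxel is foreground iff its grey value lies in
   an inclusive band `[grey_lo, grey_hi]`. The band depends on the
   instrument and reconstruction and is always explicit configuration.
2. **Labelling** — maximal connected components under 26-connectivity
   (default; thin oblique fibres fragment under 6-connectivity).
3. **Morphometry** — for each component, principal axes are the
   eigenvectors of the voxel-centre covariance. The extent along an
   axis is (max − min projected centre) + 1 voxel, so a single voxel
   has extent one voxel and no object degenerates to zero length.
   Length is the longest extent `L1`, width the mean `(L2 + L3)/2` of
   the two shorter ones, aspect ratio `L1/width`, sphericity `L3/L1`
   (1 = equal axes), and solidity the voxel volume over the volume of
   the convex hull of the voxel *cube corners*.
4. **Filtering** — in fixed order: size (voxel-count bounds), then
   sphericity cap, then solidity floor, then the strict aspect-ratio
   rule (`> 3` by default), then the border policy. The first failing
   rule is recorded, so rejection reasons are deterministic.

The per-object table, the rejection ledger, the probed volume `V_c`,
and per-stage counts are all retained (`detect_ab()`), and can be
written as CSV/JSON (`write_morphometry_csv()`, `cmd_count()`).

### Numerical choices worth knowing about

* **Degenerate principal axes.** Symmetric objects (boxes, balls,
  straight fibres) have repeated covariance eigenvalues, and the
  eigenbasis inside a repeated-eigenvalue subspace is arbitrary up to
  rotation; a careless choice reports a box's face diagonal as its
  width. `abct` snaps the basis inside each degenerate subspace to the
  nearest coordinate axes, which restores the natural basis for
  axis-aligned objects and is a no-op when eigenvalues are distinct.
* **Corner hull, not centre hull.** Building the hull on voxel centres
  can produce solidity > 1 for digitized solids (the voxel volume
  counts full cubes, the centre hull does not). The corner hull
  guarantees solidity ≤ 1, at the cost of circumscribing curved solids
  by a surface term: a digitized ball of radius 12 voxels reports
  solidity ≈ 0.886, not 1. Thresholds are calibrated under this
  convention. Before the hull is computed the voxel set is reduced to
  the cube corners of axis-line-extreme voxels, which provably contain
  every hull vertex.
* **Strictness.** The aspect-ratio rule is strict (`> 3`): an object
  with ratio exactly 3 is rejected.
* **Chunked processing.** Large volumes are split along the plane axis
  into chunks that overlap by at least the longest expected object
  (default 50 µm worth of planes). Each object is counted once, by the
  chunk owning its centroid; because the overlap bounds the object
  extent, the owning chunk contains the object entirely and chunked
  results equal whole-volume results exactly, including morphometry.
  The final chunk may overlap its neighbour by more than the nominal
  overlap when the axis length is not an exact multiple of the step.
* **TIFF subset.** Volumes are read and written as uncompressed
  grayscale multi-page TIFF stacks (8/16-bit unsigned or 32-bit float,
  either byte order on read), the format synchrotron reconstructions
  use. Values are preserved exactly (float32 precision for reals);
  anything outside this subset — compression, colour, planar layouts —
  is rejected with a specific diagnostic rather than guessed at. Voxel
  size is deliberately user metadata, never read from TIFF resolution
  tags, which are unreliable for synchrotron data.
* **Axis convention.** Data are stored `[row, col, plane]` with the
  TIFF page index as the third (rotation) axis and 1-based indices;
  chunk origins are 0-based voxel offsets, so global index = local
  index + offset.

## From counts to burden per gram of dry lung

With `N_c` accepted bodies in a probed volume `V_c` (cm³), the burden
per gram of dry lung is

```
N_gdw = (N_c / V_c) * D_dw / (V_s * O_c * R_wv)
```

with `V_s` the volumetric shrinkage from formalin-fixed to
paraffin-embedded tissue (2.3, dimensionless), `R_wv` the wet weight
per unit fixed-tissue volume (0.916 g/cm³), `D_dw` the wet-to-dry mass
ratio (≈ 10, measurable with `compute_ddw()`), and `O_c` the
orientation correction. The published account of this relation also
equates it to `N_g × D_dw` written as a bare fraction; only the form
above is numerically consistent with the published per-case
conversions (e.g. 1.43 × 10⁶ cm⁻³ → 6.79 × 10⁶ g_dw⁻¹ against a
printed 6.80 × 10⁶), so `abct` implements this form.

`O_c` exists because a body counted in a thin section of thickness `T`
is seen in more than one consecutive section when its projection
normal to the section exceeds `T`. Under orientations uniform on the
sphere the expected count per section is proportional to
`T + L·E|cos θ|` with `E|cos θ| = 1/2`, giving `O_c = 1 + L/(2T)`.
This slab-intersection model is this package's reconstruction of the
classical correction; it is validated against its own Monte-Carlo
oracle (uniformly oriented segments dropped through a slab) in the
test suite, and it is exactly 1 for a 3D volume — the point of
counting tomographically. Replicate statistics use the sample (n − 1)
standard deviation, appropriate for the typical three replicate
volumes per case.

```{r}
convert_to_gdw(2.35e6, conversion_factors())
orientation_correction(20, 5)   # 20 um bodies counted in 5 um sections
```

## The phantom generator

`phantom_spec()` + `sample_fibre_population()` + `render_phantom()`
produce volumes that emulate the features of real tomograms the
pipeline actually exploits, with exact ground truth:

* **Fibres** are capsules (cylinders with hemispherical caps) with
  log-normal lengths, truncated-normal widths, orientations uniform on
  the sphere, and sinusoidal radius modulation imitating the beaded or
  segmented coating. Beads dip *inward* from the width envelope, so a
  ground-truth record's width is the true outer width of the rendered
  body. Placement is rejection sampling: every capsule fits inside the
  volume and clears every other fibre by ≥ 2 voxels, so ground-truth
  count equals 26-connected component count by construction.
* **Context** is a uniform tissue grey with dark spherical voids
  (airways/alveoli), small bright blobs (particulate below the size
  filter) and large bright spheres (dense structures caught by the
  sphericity filter); bright distractors are placed with the same
  clearance rule so they never fuse with a fibre. Gaussian grey noise
  is added last. Everything is deterministic given the spec seed.

Default parameters are chosen to emulate the study conditions reported
for real tissue: voxel 0.332 µm; lognormal lengths with
`meanlog = log(20)`, `sdlog = 0.3` (population mean ≈ 20.9 µm, within
the reported 19.4–23.6 µm range); generative widths ~N(3.1, 0.25) µm,
chosen so that the pipeline's extent-convention measurement (outer
envelope + 1 voxel) reads ≈ 3.4 µm, matching the reported transversal
dimensions of 3.3–3.6 µm; grey model tissue 0.30 / voids 0.05 / AB and
distractors 0.90 / noise SD 0.05 on a [0, 1] scale, with the contract
that the AB grey exceeds tissue by at least 5 noise SDs. Void radii
(10–25 µm) are scaled down from real airspaces (125–150 µm radius),
which cannot fit the 85 µm default grid.

What the phantom does **not** emulate — and hence what passing recovery
tests do not certify about real data: phase-contrast fringes and
reconstruction artefacts, capillary-bed texture, spatially clustered
bodies on alveolar walls (a simple clustered placement mode exists,
but no quantitative clustering model is claimed), curved or branching
fibres, partial-volume grey blending, and calibrated grey levels. Real
deployments must recalibrate the segmentation band and filter
thresholds per instrument.

```{r, eval = FALSE}
spec <- phantom_spec(seed = 1)          # 256^3 voxels, 120 fibres
rec <- sample_fibre_population(spec)
vol <- render_phantom(rec, spec)
tab <- detect_ab(vol, segmentation_params(), filter_params())
match_truth(tab, rec)[c("sensitivity", "fdr")]
```

On this default phantom the pipeline reaches sensitivity ≥ 0.95 with
zero false discoveries, and recovers the mean length within a voxel or
a few percent; the residual misses are genuine short fibres whose
measured aspect ratio falls below the strict > 3 rule — the same
truncation the published morphometry acknowledges for real bodies.

## Morphometry statistics

`box_summary()` reports quartiles by linear interpolation between
order statistics (the `quantile()` type-7 rule; the convention is
recorded in the output), fences at quartiles ± 1.5 × the
inter-quartile distance, whiskers at the extreme data values inside
the fences, and each value beyond the fences individually as an
outlier. `fit_lognormal()` uses the closed-form maximum-likelihood
estimates on the log scale (divisor n) and reports the
Kolmogorov–Smirnov distance against the fitted curve without a
p-value — the claim being summarized is distributional shape, not a
test decision.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `grey_lo`, `grey_hi` | 0.6, 2.0 | grey | foreground band (instrument-specific) |
| `min_size_vox`, `max_size_vox` | 200, 2×10⁵ | voxels | reject particulate / large dense structures |
| `max_sphericity` | 0.5 | — | cap on `L3/L1` |
| `min_solidity` | 0.5 | — | floor on volume / corner-hull volume |
| `min_aspect_ratio` | 3 | — | strict floor on length/width |
| `connectivity` | 26 | — | component neighbourhood |
| `border_policy` | include | — | objects touching volume faces |
| `V_s`, `R_wv`, `D_dw`, `O_c` | 2.3, 0.916, 10, 1 | —, g/cm³, —, — | burden conversion factors |

The size/shape defaults are phantom-calibrated working values: the
original study's per-instrument settings are not published, and grey
thresholds in particular cannot transfer between instruments.

## Problem sizes used in the tests

The shipped suite exercises the full pipeline on 256³-voxel phantoms
with 120 fibres (the recovery study), 128×128×320 phantoms for
chunk-stitching equivalence, 100 random masks up to 32³ for
labelling-oracle equivalence, 2×10⁵ Monte-Carlo segments per grid
point for the orientation model, and 10⁴ synthetic lengths for the
log-normal recovery — sizes chosen so the whole suite runs in a few
minutes on one CPU while leaving no stage untested at scale.

## Known limitations

* Uncoated fibres (diameter ≈ 0.1–0.4 µm) are below micro-CT
  resolution; the package counts *bodies*, not bare fibres, and does
  no chemical identification.
* Solidity depends on the corner-hull convention above; values are not
  interchangeable with centre-hull or marching-cubes solidity from
  other software.
* Whether bodies touching the volume boundary should be counted is a
  study-design question; the flag is always recorded and the policy is
  explicit (`border_policy`), defaulting to include.
* The clustered placement mode is qualitative; no spatial statistics
  of real AB clustering are modelled.
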