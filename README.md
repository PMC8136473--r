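# abct — automated asbestos-body counting and morphometry in micro-CT volumes

Asbestos bodies (AB) — asbestos fibres coated in vivo with an
iron-protein sheath — are the standard accessible marker of asbestos
exposure, reported as bodies per gram of dry lung (g_dw). Conventional
counting reads tissue digests or thin histological sections under a
microscope: slow, reader-dependent, and stereologically approximate.
X-ray phase-contrast micro-tomography images the bodies directly in 3D
inside bulk tissue, so the count is exact and every body's morphometry
comes for free.

`abct` is an R package for the computational side of that workflow,
aimed at imaging scientists and pathology researchers working with
reconstructed tomographic volumes:

* **Volume I/O** — multi-page TIFF stacks (8/16-bit unsigned, 32-bit
  float), overlap-aware chunking of large volumes, slab projections for
  QC.
* **Detection** — grey-level segmentation, 3D connected-component
  labelling (6/18/26-connectivity, compiled), per-object morphometry
  (principal-extent length/width, sphericity `L3/L1`, convex-hull
  solidity) and an ordered filter cascade (size → sphericity →
  solidity → strict aspect ratio > 3 → border policy).
* **Burden** — replicate number densities `N_c/V_c` with mean ± SD and
  the stereological conversion

  `N_gdw = (N_c / V_c) · D_dw / (V_s · O_c · R_wv)`

  with shrinkage `V_s = 2.3`, wet-weight-to-volume `R_wv = 0.916
  g/cm³`, wet-to-dry mass ratio `D_dw ≈ 10`, and orientation
  correction `O_c = 1 + L/(2T)` for thin sections — exactly 1 for 3D
  volumes.
* **Statistics** — box summaries with 1.5 × IQR fences and closed-form
  log-normal length fitting.
* **Phantoms** — a synthetic generator (beaded capsule fibres,
  air voids, particulate distractors, Gaussian noise) with exact
  per-fibre ground truth, so the whole pipeline is testable without
  real tomograms.

## Worked example

Generate a phantom, run detection, and convert the count to a burden:

```r
library(abct)

spec <- phantom_spec(extents = c(128, 128, 128), n_fibres = 15, seed = 42)
rec  <- sample_fibre_population(spec)
vol  <- render_phantom(rec, spec)
vol
#> <ab_volume> 128 x 128 x 128 voxels @ 0.332 um
#>   physical extents: 42.5 x 42.5 x 42.5 um (V_c = 7.674e-08 cm^3)

tab <- detect_ab(vol, segmentation_params(), filter_params(), verbose = TRUE)
#> segmented 120609 voxels -> 35 components -> 17 after size -> 15 after shape -> 14 accepted
tab
#> <ab_table> 14 accepted / 35 components in V_c = 7.674e-08 cm^3
#>   mean length 21.15 um, mean width 3.29 um, density 1.82e+08 cm^-3

match_truth(tab, rec)[c("sensitivity", "fdr")]
#> $sensitivity [1] 0.9333333   $fdr [1] 0

burden_result(nrow(tab$accepted), tab$V_c_cm3)
#> <ab_burden> 1 replicate(s): mean 1.82e+08 cm^-3 (SD NA)
#>   N_gdw = 8.66e+08 per g dry lung (exceeds ERS 1e3/g_dw: TRUE)

morphometry_report(tab)$length_fit
#> <ab_lognormal_fit> n=14 mu_log=3.0222 sigma_log=0.2483 (KS distance 0.1973)
```

Reading: the 35 segmented components are pruned by the size filter
(particulate) and the shape filters (spherical distractors) down to 14
accepted bodies; 14 of the 15 planted fibres are recovered (the miss is
a short fibre whose measured aspect ratio is below the strict > 3
rule) with no false discovery. The tiny phantom volume (7.7 × 10⁻⁸
cm³) makes the density — and hence the converted burden — look
enormous; on real ~5 × 10⁻⁴ cm³ acquisitions the same algebra yields
burdens of order 10⁶–10⁷ per g_dw.

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "abct.R", package = "abct"))') \
    convert --density 2.35e6
# 11154357.32
```

with subcommands `phantom`, `count` (TIFF + JSON config in, morphometry
CSV + burden JSON out), `convert`, and `show-config`.

## Package layout

* `R/`, `src/` — implementation (R with two Rcpp kernels: 3D labelling
  and 3D convex hull).
* `vignettes/ab-counting-methods.Rmd` — models, conventions,
  parameter meanings and limitations.
* `tests/testthat/` — unit, property and acceptance suites.
* `inst/cli/abct.R` — command-line front end.
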