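---
title: "rhizolight: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rhizolight: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rhizolight reconstructs and quantifies light-sheet fluorescence microscopy
(LSFM) volumes of plant roots growing in transparent soil mesocosms, and
ships a seeded synthetic-mesocosm generator so that every stage of the
pipeline — reconstruction, segmentation, and colonization quantification —
can be validated against a known ground truth without access to the
instrument. This vignette documents the models, the tunable parameters, the
numerical choices, and the limits of what the phantom can demonstrate.

## The imaging model

The instrument sweeps a sealed cuboid chamber (default 22 × 65 × 3 mm,
4,290 mm³) through a Gaussian light sheet along an axis at 45° to the
illumination and detection axes, recording three signals: elastic scattering
from the root, sulforhodamine-B fluorescence from the soil particles, and GFP
fluorescence from labelled bacteria. The forward model implemented by
`render_scan()` is, in order:

1. **PSF blur.** A separable Gaussian with axial (sheet-thickness) FWHM
   50 µm and a lateral FWHM set by the effective sampling (default 50 µm),
   truncated at 3σ and normalized (`make_lightsheet_psf()`). No wave-optical
   sheet propagation is modelled; the sheet is treated as having constant
   thickness across the field, ignoring beam divergence (the instrument's
   Rayleigh range is long compared to the chamber depth, and the exact
   usable range is not modelled here).
2. **Sheared sampling.** Frame *k* of a pass samples the plane
   z = k·Δs·cosθ, displaced by k·Δs·sinθ along the frame rows (Δs = stage
   step, θ = scan angle). By default Δs = voxel/cosθ, so each slice lands
   exactly one truth voxel deeper and, at 45°, the per-slice shear is exactly
   one voxel: the shear matrix is exactly invertible in floating point, and
   `shear_correct()` (nearest-neighbour inverse shear) is its exact inverse.
   Voxels never observed by a pass (the sheared corners) are marked `NA`.
3. **Detection artifacts.** Each frame is multiplied by a smooth separable
   quadratic vignetting field (corner minimum configurable, default off /
   0.6 when exercised), scaled by the photon gain, offset, and perturbed by
   Gaussian read noise. All randomness flows from a single integer seed;
   identical seeds give bit-identical tiles.

Tiles overlap by a configurable fraction (default 20%) along the scan
directions.

## Reconstruction

`reconstruct_volume()` chains four stages:

* **Flat-field correction** (`estimate_flatfield()` / `apply_flatfield()`).
  Soil is a textured material: the stained-particle population is a
  spatially repeating structure whose modal brightness is stationary, so the
  per-pixel histogram mode over a whole frame dataset (9 px neighbourhood,
  bin width 1/256 of the dynamic range) estimates the illumination/detection
  field, and the weight matrix is the global reference mode over the local
  mode, clipped to [0.2, 5]. Because the unstained pore space would dominate
  the histograms in a porous scene, values below an Otsu split of the
  dataset are excluded by default. The weight matrix is estimated once from
  the particle channel and shared by all channels of the same camera; the
  GFP channel cannot be used for its own estimate because its spatial
  structure is real signal, not texture. Correction is applied per Laplacian
  pyramid band (3 levels by default) with optional per-band gains; with unit
  gains the correction is exactly multiplicative.
* **Shear correction**, as above.
* **Stitching** (`stitch_tiles()`). Tile origins are refined by
  integer-shift cross-correlation in the pairwise overlap zones (search
  radius ±5 voxels; registration uses the particle channel because it is the
  most textured). Sub-voxel registration is deliberately out of scope.
  Tiles are then fused by Laplacian-pyramid blending with distance-feathered
  weights: each tile's weight is the squared Euclidean distance to its data
  boundary (squaring keeps smoothed coarse-level weights near zero at the
  boundary, which limits leakage of extrapolated fill content; the residual
  flux error of the blend is below 1%). Pyramid depth defaults to
  ⌊log₂(min overlap extent)⌋ − 1, at least 1 and at most 4. Tiles are
  processed in canonical origin order, so the result is independent of the
  input order. Band-pass ringing can undershoot zero; the blend is clipped
  at 0 to preserve the non-negativity contract of intensity volumes.
* **Richardson–Lucy deconvolution** (`lr_deconvolve()`), 10 iterations by
  default, no regularization, reflective edge handling through the
  convolution boundary rule. The estimate stays non-negative, conserves
  total intensity within 1%, and its Poisson likelihood is non-decreasing
  across iterations — all three are asserted by tests on every release.

## Segmentation

* **Root**: seeded region growing (flood fill at or above a global
  threshold, 26-connectivity by default to bridge 1-voxel diagonal gaps in
  the scattering signal), keeping the largest seed-connected component,
  followed by a radius-1 morphological closing. The homogeneity criterion is
  a fixed global threshold; an adaptive criterion may behave differently on
  real data and this choice is flagged, not assumed. Seeds default to the
  brightest scattering voxel.
* **Pore space**: sulforhodamine attaches only superficially to particles,
  so the particle channel alone under-reports particle interiors. The
  inverted GFP signal (bacteria live in the pore liquid) is min–max
  normalized and averaged with the normalized particle channel (equal
  weights; degenerate constant channels are dropped from the average), the
  composite is thresholded (manual, with Otsu initialization) and closed
  (dilation then erosion, radius 1). Pores are the complement of particles
  and root.
* **Pore size**: the local thickness metric — for each pore voxel, the
  diameter of the largest sphere fully contained in the pore phase that
  contains the voxel. Implemented on the exact anisotropic Euclidean
  distance transform with redundant-sphere pruning and sphere painting;
  the grid border counts as solid. On grids up to 32³ the result equals an
  exhaustive all-centres search exactly (this equivalence is a standing
  test).

## Quantification

Every analyzed voxel at every time point carries three variables: pore size,
distance from the root surface (exact anisotropy-aware EDT), and distance
from the root tip. The centerline is the longest geodesic path through the
root mask (Dijkstra, 26-neighbour physical metric, lightly smoothed); the
tip is the end farthest from the base, so lengths are measured apex-to-apex,
and each voxel inherits the arc-length-from-tip of its nearest centerline
node.

GFP intensity converts to cell density through two fitted regressions
emulating the suspension calibration protocol (12 dilutions spanning OD600
1.2 × 10⁻³ – 3.0): intensity = a·OD + b (ordinary least squares) and
CFU = c·OD (through the origin), giving density = c·(I − b)/a clipped at
zero. Suspension calibration may underestimate density in biofilms; no
biofilm correction is attempted.

Voxels are classified into groups (schemes: distance-from-root bins of
100 µm; rhizosphere < 0.2 mm vs bulk; distance-from-tip bins of 500 µm;
tip vs base at 2 mm; pore-size bins of 100 µm). Binning is half-open
[lo, hi), boundary values fall upward. Radial schemes are restricted to a
3 mm-diameter cylinder around the centerline. For each group Rk at time t,
`compute_indicators()` reports the mean density D (optionally per unit
volume of segmented root at that time — a flag, since the exact published
normalization equation is not available in the text used here), the
normalized density D/⟨D⟩ with ⟨D⟩ the mean over the scheme's groups at fixed
time (a spatial mean; the stated purpose of the normalization is comparing
patterns independently of colonization magnitude, and a temporal-mean
alternative is exposed as a flag), and the mobility indicator: the temporal
variance of D/⟨D⟩ after discarding the first five time points. Variance is
computed on the normalized density so replicate-scale differences cancel.

`kinematics_diagram()` maps mean density over (distance-from-tip bin × time);
a hotspot fixed in the laboratory frame appears as a diagonal stripe whose
slope is the elongation rate (`stripe_slope()` fits it by tracking the
densest bin). `timeseries_summary()` reports rhizosphere, bulk and whole-soil
mean densities over time with plateau-tolerant peak detection (tolerance 1%
of the series range — a tie-breaker for numerical plateaus, not a biological
smoothing). Pulse periodicity is estimated by autocorrelation after removing
the slow colonization trend with a loess fit (span 0.5); a quadratic detrend
is too stiff for the Gaussian-shaped colonization envelope and masks the
pulse lag.

## The phantom generator

The generator encodes the study conditions and is not tuned per run:

* **Chamber** 22 × 65 × 3 mm (reduced chambers are used in tests as the
  stated problem size, not as a change of conditions).
* **Particles**: spheres with diameters uniform in 0.25–1.25 mm (sandy-soil
  grain sizes of the fractured substrate), packed largest-first by random
  sequential addition. The default target porosity is 0.60 — a loosely
  packed granular bed, chosen once because it is realistic for a poured,
  polydisperse packing and lies comfortably inside what sequential addition
  can reach; candidates that overshoot the remaining solid deficit are
  resampled smaller so the achieved porosity lands within one
  minimum-particle volume of the target. Unreachable targets fail loudly,
  naming the achieved porosity.
* **Root**: a straight tube of radius 250 µm elongating at 100 µm/h from an
  initial 2 mm seedling length (a few mm/day, typical of lettuce seedlings
  in such mesocosms), truncated with a warning at the chamber wall. No
  branching or root hairs.
* **Bacterial field** (CFU/mL; a continuous density, not discrete cells —
  the imaging quantifies density, not individual cells): the sum of a
  background term whose temporal envelope peaks at 26 h post inoculation
  (Gaussian, σ = 6 h), a near-root accumulation term decaying exponentially
  with distance from the root surface and peaking at 32 h (σ = 5 h), and
  Gaussian hotspots (default 6, radius 300 µm, Poisson-disc placed in the
  pore space with 1.5 mm minimum separation) pulsing on the schedule
  (t mod 4 h) < 2 h, with amplitude following the bulk envelope — hotspot
  activity tracks overall colonization. The accumulation e-folding scale is
  300 µm, which places ~96% of the near-root mass within 1 mm of the root
  and keeps the emergent bulk curve (mean density of soil beyond 0.2 mm,
  the measurement's own definition) peaking at the programmed 26 ± 1 h.
  Voxels in pores thinner than 400 µm carry 3× the density; the field is
  zero outside the pore space. Pulses are synchronized (per-hotspot phase
  jitter exists but defaults to off).
* **Fluorescence forward model**: GFP intensity a·(density/c) + b with
  a = 1000 counts/OD, b = 50 counts, c = 2 × 10⁸ CFU·mL⁻¹/OD — chosen so
  that densities of 10⁶–10⁸ CFU/mL span a realistic fraction of the camera
  range above the offset.

What the phantom does **not** emulate: refractive-index mismatch and
scattering artifacts, depth-dependent sheet broadening, chromatic offsets
between channels, root growth curvature or gravitropism, discrete bacteria
and biofilm optics, and stage positioning error beyond integer-voxel
offsets. Passing the phantom suites therefore demonstrates the correctness
of the computational chain under its stated forward model, not instrument
performance on real mesocosms.

## Problem sizes and numerical choices

Test and acceptance runs use reduced chambers — 4 × 6 × 2 mm (2 × 2-tile
reconstruction fidelity) and 5 × 10 × 2 mm over 23 hourly time points
(indicator recovery) — at 50 µm truth voxels; these sizes resolve the 400 µm
pore-bias threshold with ~8 voxels per smallest grain diameter and keep a
full series tractable on a laptop-class machine. Oracle-equivalence checks
run on grids up to 32³, where exhaustive brute force is feasible.

Degenerate inputs are contracts, not surprises: empty root masks and
empty pore masks error or warn explicitly; seeds below the threshold name
the offending voxel; constant-zero flat-field datasets, non-positive
calibration slopes and OD ranges narrower than a decade are rejected;
unsorted bin edges and non-increasing time vectors are parameter errors;
out-of-data voxels are `NA` internally and 0 (with a validity attribute) on
export. Ties in registration are broken toward the smallest shift; the
pyramid upsampler normalizes by the interpolated sampling mask so constants
are reproduced exactly at boundaries.

## Known limitations

* The shear inverse uses nearest-neighbour interpolation (as in the
  processing it models); sub-voxel structure on non-voxel-aligned scan
  steps is quantized accordingly.
* Local thickness sphere painting is exact but can be slow on very large,
  very open pore systems; the pruning keeps typical packings fast.
* The fixed-threshold region-growing criterion and the equal-weight
  inverse-GFP composite are documented choices where the published
  description is not specific; both are exposed as parameters.
* Indicator variance is reported per group over the retained time points
  only; no inference across biological replicates is provided beyond the
  per-group summaries.
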