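---
title: "nemaquant: methods, parameters, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nemaquant: methods, parameters, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nemaquant)
```

## What the package models

`nemaquant` emulates a NEMA IEC body-phantom quantification experiment in
software. The phantom holds six fillable spheres (inner diameters 10, 13,
17, 22, 28, 37 mm), a 51-mm cylindrical lung insert on the phantom axis,
and a warm background compartment; sphere-to-background ratios (SBRs) of
no background (NB), 5:1, 2.5:1 and 1.25:1 span the clinically relevant
range from lung-adjacent lesions (essentially no background) down to
spleen-like backgrounds where lesions nearly vanish. The pipeline
simulates SPECT-like and PET-like images of this phantom, segments the
spheres with the three standard methods, and quantifies activity
concentration and volume as recovery coefficients (RC = measured / true).

The simulator is an *image-domain* emulator. It does not model
projections, attenuation, scatter, or iterative reconstruction; the net
effect of the reconstruction chain on a clinical image is reduced to a
stationary Gaussian point spread function (PSF) plus stationary noise.
That reduction is what makes desk-scale studies possible, and it is also
the boundary of what a green test here can establish (see *Limitations*).

## Phantom geometry and rasterization

Sphere centers are coplanar on a 114.4-mm circle in the transaxial plane
`z = 0`, 60° apart, largest sphere at 0° — the standard layout for this
phantom; the sources describing the physical experiment do not fix the
angular origin, so it is a configuration value. The torso cross-section
is approximated as a 300 × 230 mm stadium (two half-discs joined by a
straight section) extruded 180 mm in z. The exact torso outline is a
licensed engineering drawing; quantification depends on it only through
the background-ROI placement margins, and the approximation is recorded
in the serialized geometry config.

Rasterization (`voxelize()`) is partial-volume exact: voxels whose full
extent lies clearly inside or outside a compartment (decided by signed
distance vs. the voxel half-diagonal) get fractions 1/0 analytically;
only boundary voxels are subsampled (`subsampling^3` points, default 4³ =
64). Fractions over all compartments (including `outside`) sum to 1 at
every voxel by construction; compartment volumes converge to the analytic
values as subsampling grows (≤ 1% error for a 10-mm sphere on a 1-mm grid
at subsampling 5).

Coordinates are right-handed, in mm; a voxel's coordinate is its center;
axial slices are constant-z planes. When a sphere center falls exactly
midway between two slices, the lower slice index wins (relevant to the
CT-based ROI).

## Imaging simulator

The chain is: compose the partial-volume-exact activity map (kBq/mL) →
Gaussian blur → unit conversion → noise.

Tunable parameters, defaults, and why:

* **Grids.** `spect-in111`: 64 × 64 × 31 voxels at 9.3 mm isotropic
  (voxel volume 0.80 cm³). `pet-ga68` / `pet-f18`: 3.65 × 3.65 × 3.27 mm
  voxels (0.044 cm³), on a 95 × 75 × 69 grid sized to the phantom plus a
  ≥ 3·FWHM margin rather than the scanner's full field of view — identical
  voxel geometry, ~7× fewer voxels.
* **PSF FWHM** (mm): 12 (SPECT-like, medium-energy-collimator regime) and
  6.5 (PET-like with a typical post-filter). The underlying clinical
  protocols do not state their reconstructed resolution, so these are
  explicit assumptions, chosen mid-range for their modality class, and
  are configuration values, not constants.
* **Positron-range surrogate** `extra_blur_fwhm`: 2.5 mm for the
  ⁶⁸Ga-like preset, 0 for ¹⁸F-like and SPECT-like. The physical
  difference between ⁶⁸Ga and ¹⁸F (maximum positron energy ~1.9 vs
  0.63 MeV) is reduced to this single extra blur; the package asserts
  only the *direction* (⁶⁸Ga recovery ≤ ¹⁸F recovery), never a percentage.
* **Noise**: Gaussian, sd = 2% (PET-like) or 5% (SPECT-like) of the image
  maximum — stand-ins for "noise comparable to lesion-free liver", which
  is not otherwise quantified. A Poisson mode (`counts-per-value` scale)
  is available for count images. One seed controls each image's noise
  draw; identical seed + inputs give identical images.
* **SPECT calibration**: concentration → expected counts via
  `sensitivity_factor` (default 10 cps per MBq per voxel) × voxel volume ×
  `duration_s`. The per-angle timing of a real step-and-shoot acquisition
  is collapsed into one effective per-voxel duration (default 1800 s);
  only the product matters for the round trip, and the calibration tests
  recover the factor exactly from a simulated uniform scan.
* **Activity**: all spheres share one concentration (default 20 kBq/mL,
  a realistic phantom fill), background = sphere / SBR, lung cold.
  Concentrations are decay-corrected by assumption.

Blur is separable with kernels truncated at 4σ and normalised, acting in
physical units; it conserves the image integral to < 0.5% for objects
≥ 3·FWHM from the grid edge, and a constant image is a fixed point.

## Segmentation

Three methods, as used on real phantom data:

1. **Plain threshold**: absolute level `T · AC_max`, `T ∈ (0, 1]`.
2. **Background-adapted threshold**: `T_adapt = T · (AC_max − BG) + BG`.
3. **CT-based ROI**: a geometry-derived single-slice disk at the sphere's
   inner border in the slice through its center (the ROI one would draw
   on CT and copy into the emission image). A full 3-D sphere mask is
   available as method `"ct3d"` for comparison, but the single-slice form
   is the default because that is how such ROIs are used in practice.

Decisions the method descriptions leave open, resolved here and recorded
in output provenance:

* **AC_max** is the maximum inside a *search region* — a cube of side
  twice the sphere diameter centered on the nominal sphere center —
  evaluated *before* mask growth. (Defining AC_max "in the VOI" is
  circular; the search region breaks the circle.)
* **Connectivity**: the VOI is the 26-connected component of
  super-threshold voxels containing the maximum voxel.
* **BG** is the mean of three 15-mm cubic ROIs at 120° spacing in the
  sphere plane, 90 mm from the axis — between the spheres and the phantom
  edge, ≥ 15 mm clear of every sphere surface, the lung insert and the
  body wall (verified at run time). On cold backgrounds, noise can push
  the estimate below zero; it is floored at 0, keeping the estimate a
  valid concentration.
* **Infeasibility is a result, not an error.** A sphere is reported
  non-segmentable when `AC_max ≤ BG`, when the component is empty, or
  when the grown component touches the search-region boundary (i.e. the
  threshold has flooded into the background). Sweeps keep infeasible
  rows, flagged, matching how low-SBR spheres fail on real images.

Properties maintained (and tested): masks are nested in `T`; the adapted
level is ≥ the plain level whenever `BG > 0`, so adapted masks are subsets
of plain masks at equal `T`; region growth agrees with an independent
minimum-label-propagation flood fill on random volumes.

## Quantification

`quantify()` reports AC_max, AC_mean, and volume = voxel count × voxel
volume over the mask. Recovery coefficients divide by the *configured*
truth (the simulation's activity config, or user-supplied truth for
external images) — never by anything measured from the image itself.

`sweep_thresholds()` enumerates sphere × T (default 10–90% in 10% steps).
`select_best_threshold()` implements two criteria:

* **concentration**: per (method, SBR), the `T` minimising the *median*
  over feasible spheres of `|RC_mean − 1|`. "Best for the majority of the
  spheres" is not a fully specified aggregation; the median is a robust
  reading of it, and the criterion function is swappable.
* **volume**: per sphere, the `T` minimising `|volume − true volume|`.

Ties go to the lower `T` in both cases.

On the default noiseless PET-like NB image the volume-criterion best
threshold for the 37-mm sphere lands at ~0.43, rising for smaller
spheres — the classic threshold-vs-size curve. Monotonicity is asserted
on the 10%-step grid: on much finer grids the per-sphere best threshold
wiggles by a few percent for spheres only a few voxels across, because
adding or removing a single voxel changes their volume by several
percent.

## Detectability

`line_profile()` samples the image by trilinear interpolation (default
step: half the smallest voxel dimension; default endpoints: through the
37- and 17-mm sphere centers). `peak_contrast()` scores
`(peak − BG) / noise_sd` and flags "detectable" at ≥ 4 — a Rose-criterion
convention, configurable, and *not* calibrated to human reads. At the
default SPECT-like noise (5%) and SBR 1.25:1 the 37-mm sphere scores a
mean just below 4 across seeds — at the edge of detectability, consistent
in direction with profiles showing no usable peak on real images at that
contrast, but clearly a point where the stand-in noise model, not the
physics, sets the number.

## What the synthetic data does and does not establish

The generator emulates: the phantom geometry; partial-volume effects at
the two clinical voxel scales; resolution loss as stationary Gaussian
blur; calibrated count images; stationary noise of roughly clinical
magnitude. It does **not** emulate: Gibbs ringing from PSF-modelling
reconstruction (which inflates real maxima), spatially varying
resolution or noise correlations from iterative reconstruction, scatter
and attenuation-correction residuals, dead time, or radionuclide physics
beyond one extra blur term. Consequently, green tests establish that the
*procedures* behave correctly and that the *directions* of the classic
effects (spill-out, spill-in, threshold-vs-size, modality contrast) are
reproduced; they do not reproduce scanner-specific recovery-curve values,
which depend on the reconstructions themselves.

## Numerical choices

* Blur kernels truncated at 4σ, renormalised (zero-padding beyond grid).
* Boundary-voxel subsampling default 4³; rasterization exactness
  degrades gracefully to ~1–2% volume error at the PET voxel scale.
* Nearest-slice ties resolve to the lower index; best-threshold ties to
  the lower `T`.
* Degenerate CT ROIs (no voxel center within the disk — possible for the
  10-mm sphere on the 9.3-mm SPECT grid) fall back to the single voxel
  containing the sphere center rather than returning an empty mask.
* RNG: every stochastic stage takes an explicit seed and restores the
  caller's RNG state; batch runs derive per-replicate seeds
  deterministically.

## Known limitations

* The stadium body outline is an approximation; absolute background-ROI
  positions would differ slightly on the true torso cross-section.
* The Gaussian-PSF / stationary-noise reduction understates the maxima
  of PSF-reconstructed clinical images (no Gibbs overshoot) and ignores
  noise correlation, so max-in-VOI recoveries here are closer to 1 than
  scanner measurements at matched nominal resolution.
* Configuration files are JSON (no YAML dependency); images are NIfTI-1
  via a minimal built-in reader/writer (float32/uint8, sform only).
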