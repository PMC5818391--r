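# nemaquant

Synthetic NEMA IEC body-phantom imaging and quantification for emission
tomography.

## The problem

Quantifying the activity concentration and volume of a hot lesion in SPECT
or PET is limited by the partial-volume effect: the imaging chain's point
spread function (PSF) spills signal out of small objects (and spills
background activity in), so the measured concentration and any
threshold-derived volume depend strongly on object size, on the
sphere-to-background ratio (SBR), and on the segmentation method. The
standard way to characterise this is the NEMA IEC body phantom: six
fillable spheres (inner diameters 10, 13, 17, 22, 28 and 37 mm; volumes
0.5–26.5 cm³), a 51-mm cylindrical lung insert, and a torso-shaped warm
background.

`nemaquant` lets you study detectability and quantification accuracy
without a scanner. It provides:

* an **analytic phantom model** with exact (sub-voxel) rasterization,
* a **SPECT-like / PET-like simulator**: partial-volume-exact activity map
  → Gaussian PSF blur → unit calibration (counts via a sensitivity factor,
  or kBq/mL directly) → seeded Gaussian/Poisson noise,
* the three standard **segmentation methods**: fixed-fraction threshold
  VOIs, background-adapted threshold VOIs, and CT-based reference ROIs,
* **quantification**: recovery coefficients, threshold sweeps,
  best-threshold selection, volume estimation, line profiles and a
  contrast-to-noise detectability score,
* a batch **experiment runner** and a small **CLI**.

## The model in brief

* Recovery coefficient: `RC = measured / true` (for AC_max, AC_mean, or
  volume).
* Plain threshold VOI at fraction `T`: voxels with value ≥ `T · AC_max`,
  taken as the 26-connected component containing the maximum voxel.
* Background-adapted threshold:

  ```
  T_adapt = T · (AC_max − BG) + BG
  ```

  where `BG` is the mean of three background ROIs placed between the
  spheres and the phantom edge. With `BG = 0` this reduces to the plain
  threshold; with `T = 1` it equals `AC_max`.
* SPECT-like calibration: a uniform-phantom scan gives the sensitivity
  factor (cps per MBq per voxel) as mean counts per voxel normalised by
  duration, concentration and voxel volume; `counts_to_concentration()`
  inverts it.

## Worked example

```r
library(nemaquant)
geom <- default_nema_geometry()
ps   <- preset("pet-ga68")                         # 3.65 x 3.65 x 3.27 mm
fm   <- voxelize(geom, ps$grid)
act  <- activity_from_sbr(5, sphere_kBqml = 20)    # SBR 5:1
img  <- simulate_phantom(geom, ps$grid, act, ps$acq, seed = 1,
                         fractions = fm)

bg  <- estimate_background(img, geom)
voi <- segment(img, geom, "sphere_28mm", method = "adapted", T = 0.5)
q   <- quantify(img, voi)
rc  <- recovery_curve(img, geom, act, method = "ct", statistic = "mean")
```

This prints (seed 1):

```
background estimate: 3.95 kBq/mL (true 4.00)
voi_mask [adapted] sphere_28mm: 213 voxels (9.28 cm^3), T = 0.50
AC_max 21.10, AC_mean 17.08 kBq/mL; volume 9.28 cm^3 (true 11.49)
RC_max 1.06, RC_mean 0.85
    sphere_id diameter_mm        RC feasible
1 sphere_10mm          10 0.5306663     TRUE
2 sphere_13mm          13 0.6267470     TRUE
...
6 sphere_37mm          37 0.8898932     TRUE
```

Reading this: the maximum slightly overestimates the true 20 kBq/mL
(noise picks the upper tail, background spills in), the 50%-threshold VOI
underestimates the 28-mm sphere's volume, and the CT-based mean recovery
falls from 0.89 (37 mm) to 0.53 (10 mm) — the partial-volume effect in
its classic form.

The full experiment matrix (2 modality presets × 4 SBR levels × seeds,
all three methods, the 10–90% threshold grid) runs with:

```r
run_experiment(experiment_plan(out_dir = "runs/demo"))
```

and writes `sweep_table.csv`, `line_profiles.csv`, `best_thresholds.csv`
and `manifest.json`.

## Command line

```sh
inst/cli/nemaquant simulate --preset pet-ga68 --sbr 5 --seed 1 --out img.nii
inst/cli/nemaquant segment  --image img.nii --sphere sphere_28mm \
                            --method adapted --threshold 0.5 --out mask.nii
inst/cli/nemaquant quantify --image img.nii --mask mask.nii
inst/cli/nemaquant run      --out runs/full
```

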