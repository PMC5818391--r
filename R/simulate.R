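# SPECT-like / PET-like image synthesis: partial-volume-exact activity map,
# stationary Gaussian PSF, unit calibration, and seeded noise. Stands in for
# clinical acquisition + iterative reconstruction, which are out of scope.

#' Activity configuration
#'
#' Concentrations are decay-corrected kBq/mL. All six spheres share one
#' concentration (filled from the same stock solution); the background
#' compartment is warm or cold; the lung insert is cold by default.
#'
#' @param sphere_kBqml sphere activity concentration, kBq/mL.
#' @param background_kBqml background concentration; 0 means the
#'   no-background (NB) condition.
#' @param lung_kBqml lung-insert concentration (default 0).
#' @return An `activity_config` with the derived `sbr` (`Inf` for NB).
#' @export
activity_config <- function(sphere_kBqml, background_kBqml = 0,
                            lung_kBqml = 0) {
  if (sphere_kBqml < 0 || background_kBqml < 0 || lung_kBqml < 0)
    stop_invalid("concentrations must be >= 0")
  structure(list(sphere_kBqml = sphere_kBqml,
                 background_kBqml = background_kBqml,
                 lung_kBqml = lung_kBqml,
                 nb = background_kBqml == 0,
                 sbr = if (background_kBqml > 0)
                   sphere_kBqml / background_kBqml else Inf),
            class = "activity_config")
}

#' Activity configuration from a sphere-to-background ratio
#'
#' @param sbr numeric ratio (e.g. 5, 2.5, 1.25) or `"NB"` / `Inf` for the
#'   no-background condition.
#' @param sphere_kBqml sphere concentration, kBq/mL.
#' @export
activity_from_sbr <- function(sbr, sphere_kBqml = 20) {
  if (identical(sbr, "NB") || is.infinite(sbr))
    return(activity_config(sphere_kBqml, 0))
  sbr <- as.numeric(sbr)
  if (!is.finite(sbr) || sbr <= 0) stop_invalid("sbr must be positive or 'NB'")
  activity_config(sphere_kBqml, sphere_kBqml / sbr)
}

#' Noise model
#'
#' @param kind `"none"`, `"gaussian"` (additive, sd = `magnitude` x image
#'   maximum) or `"poisson"` (`magnitude` is the counts-per-value scale).
#' @param magnitude nonnegative scalar (see `kind`).
#' @param seed RNG seed; identical seed + input gives identical output.
#' @export
noise_model <- function(kind = c("none", "gaussian", "poisson"),
                        magnitude = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (magnitude < 0) stop_invalid("noise magnitude must be >= 0")
  structure(list(kind = kind, magnitude = magnitude, seed = seed),
            class = "noise_model")
}

#' Acquisition configuration
#'
#' @param modality `"spect-like"` (count images) or `"pet-like"` (kBq/mL).
#' @param psf_fwhm length-3 Gaussian PSF FWHM in mm (reconstructed
#'   resolution surrogate).
#' @param extra_blur_fwhm additional isotropic FWHM in mm (positron-range
#'   surrogate; 0 for SPECT-like and 18F-like, > 0 for 68Ga-like).
#' @param noise a [noise_model()].
#' @param sensitivity_factor cps per MBq per voxel (SPECT-like only).
#' @param duration_s effective acquisition time per voxel, seconds.
#' @export
acquisition_config <- function(modality = c("pet-like", "spect-like"),
                               psf_fwhm = c(6.5, 6.5, 6.5),
                               extra_blur_fwhm = 0,
                               noise = noise_model(),
                               sensitivity_factor = NA_real_,
                               duration_s = 180) {
  modality <- match.arg(modality)
  psf_fwhm <- rep_len(as.numeric(psf_fwhm), 3L)
  if (any(psf_fwhm < 0) || extra_blur_fwhm < 0)
    stop_invalid("PSF FWHM must be >= 0")
  if (modality == "spect-like" &&
      (!is.finite(sensitivity_factor) || sensitivity_factor <= 0))
    stop_invalid("spect-like acquisition needs a positive sensitivity_factor")
  structure(list(modality = modality, psf_fwhm = psf_fwhm,
                 extra_blur_fwhm = extra_blur_fwhm, noise = noise,
                 sensitivity_factor = sensitivity_factor,
                 duration_s = duration_s,
                 value_unit = if (modality == "spect-like") "counts"
                 else "kBq/mL"),
            class = "acquisition_config")
}

#' Modality presets
#'
#' `"spect-in111"`: 9.3 mm isotropic voxels (voxel volume 0.80 cm^3),
#' PSF FWHM 12 mm, Gaussian noise sd 5% of the image maximum, sensitivity
#' factor 10 cps/MBq voxel. `"pet-ga68"`: 3.65 x 3.65 x 3.27 mm voxels
#' (0.044 cm^3), PSF FWHM 6.5 mm plus a 2.5-mm positron-range surrogate,
#' Gaussian noise sd 2%. `"pet-f18"`: as `"pet-ga68"` without the extra
#' blur. Grids are sized to hold the phantom plus a blur margin rather
#' than the full scanner field of view.
#'
#' @param name preset name.
#' @param noise_seed seed stored in the preset's noise model.
#' @return list with elements `grid` and `acq`.
#' @export
preset <- function(name = c("pet-ga68", "pet-f18", "spect-in111"),
                   noise_seed = NULL) {
  name <- match.arg(name)
  if (name == "spect-in111") {
    list(grid = grid_spec(c(64, 64, 31), c(9.3, 9.3, 9.3)),
         acq = acquisition_config("spect-like", psf_fwhm = c(12, 12, 12),
                                  extra_blur_fwhm = 0,
                                  noise = noise_model("gaussian", 0.05,
                                                      noise_seed),
                                  sensitivity_factor = 10,
                                  duration_s = 1800))
  } else {
    list(grid = grid_spec(c(95, 75, 69), c(3.65, 3.65, 3.27)),
         acq = acquisition_config("pet-like", psf_fwhm = c(6.5, 6.5, 6.5),
                                  extra_blur_fwhm = if (name == "pet-ga68")
                                    2.5 else 0,
                                  noise = noise_model("gaussian", 0.02,
                                                      noise_seed),
                                  duration_s = 180))
  }
}

#' Compose the ground-truth activity map
#'
#' Per voxel, value = sum over compartments of occupancy fraction times the
#' compartment's concentration — the partial-volume-exact truth image.
#'
#' @param fm a [voxelize()] fraction map.
#' @param activity an [activity_config()].
#' @return An [image_volume()] in kBq/mL.
#' @export
compose_activity <- function(fm, activity) {
  if (!inherits(fm, "fraction_map")) stop_invalid("fm must be a fraction_map")
  conc <- vapply(fm$compartments, function(nm) {
    if (nm == "outside") 0
    else if (nm == "background") activity$background_kBqml
    else if (nm == "lung") activity$lung_kBqml
    else activity$sphere_kBqml
  }, numeric(1))
  vals <- array(0, fm$grid$dims)
  for (nm in fm$compartments) {
    if (conc[[nm]] != 0) vals <- vals + conc[[nm]] * fm$fractions[[nm]]
  }
  image_volume(vals, fm$grid, value_unit = "kBq/mL",
               provenance = sprintf("compose_activity sbr=%s",
                                    format(activity$sbr)))
}

# Separable Gaussian convolution along one array axis via a band matrix;
# kernel truncated at 4 sigma and normalised (zero-padding beyond the grid).
blur_axis <- function(vals, axis, sigma_mm, spacing_mm) {
  if (sigma_mm <= 0) return(vals)
  n <- dim(vals)[axis]
  halfw <- max(1L, ceiling(4 * sigma_mm / spacing_mm))
  offs <- (-halfw):halfw
  k <- exp(-(offs * spacing_mm)^2 / (2 * sigma_mm^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (j in seq_along(offs)) {
    idx <- seq_len(n) + offs[j]
    ok <- idx >= 1 & idx <= n
    K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] + k[j]
  }
  d <- dim(vals)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vals, perm)
  v <- K %*% matrix(v, nrow = d[axis])
  v <- array(v, dim = d[perm])
  aperm(v, order(perm))
}

#' Gaussian blur in physical units
#'
#' Convolves the image with a separable Gaussian of the given FWHM per axis
#' (sigma = FWHM / 2.355), zero-padded beyond the grid. FWHM 0 is the
#' identity.
#'
#' @param image an [image_volume()].
#' @param fwhm_mm length-3 (or scalar) FWHM in mm.
#' @export
blur <- function(image, fwhm_mm) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(fwhm_mm < 0)) stop_invalid("fwhm must be >= 0")
  vals <- image$values
  for (ax in 1:3) {
    vals <- blur_axis(vals, ax, fwhm_to_sigma(fwhm_mm[ax]),
                      image$grid$spacing[ax])
  }
  image_volume(vals, image$grid, value_unit = image$value_unit,
               provenance = image$provenance)
}

#' Apply a noise model to an image
#'
#' Gaussian: adds N(0, magnitude x image maximum). Poisson: draws
#' Poisson(value x magnitude) / magnitude; negative expected counts are
#' clamped to 0 with a warning. Reproducible given `noise$seed`.
#'
#' @param image an [image_volume()].
#' @param noise a [noise_model()].
#' @export
add_noise <- function(image, noise) {
  if (noise$kind == "none" || noise$magnitude == 0) return(image)
  vals <- image$values
  n <- length(vals)
  vals <- with_seed(noise$seed, {
    if (noise$kind == "gaussian") {
      vals + stats::rnorm(n, sd = noise$magnitude * max(vals))
    } else {
      lam <- vals * noise$magnitude
      if (any(lam < 0)) {
        warning("negative expected counts clamped to 0")
        lam <- pmax(lam, 0)
      }
      stats::rpois(n, lam) / noise$magnitude
    }
  })
  image_volume(array(vals, image$grid$dims), image$grid,
               value_unit = image$value_unit,
               provenance = paste0(image$provenance,
                                   sprintf(" +%s noise (seed %s)",
                                           noise$kind,
                                           format(noise$seed %||% NA))))
}

# kBq/mL concentration image -> expected counts per voxel:
# counts = factor [cps/MBq voxel] x concentration [MBq/mL] x voxel volume
#          [mL] x duration [s]
concentration_to_counts <- function(image, acq) {
  vox_ml <- voxel_volume_cm3(image$grid)  # 1 cm^3 = 1 mL
  vals <- image$values / 1000 * acq$sensitivity_factor * vox_ml *
    acq$duration_s
  image_volume(vals, image$grid, value_unit = "counts",
               provenance = image$provenance)
}

#' Simulate a phantom acquisition
#'
#' Pipeline: compose the partial-volume-exact activity map, blur by the
#' system PSF and any extra (positron-range surrogate) blur, convert to the
#' modality's value unit (SPECT-like: expected counts via the sensitivity
#' factor), then add noise.
#'
#' @param geom phantom geometry.
#' @param grid target [grid_spec()].
#' @param activity an [activity_config()].
#' @param acq an [acquisition_config()].
#' @param seed overrides `acq$noise$seed` when non-NULL.
#' @param fractions optional precomputed [voxelize()] result for this
#'   geometry/grid (reused across seeds to avoid re-rasterizing).
#' @param subsampling passed to [voxelize()] when `fractions` is NULL.
#' @return Calibrated [image_volume()].
#' @export
simulate_phantom <- function(geom, grid, activity, acq, seed = NULL,
                             fractions = NULL, subsampling = 4L) {
  if (is.null(fractions)) fractions <- voxelize(geom, grid, subsampling)
  if (!same_grid(fractions$grid, grid))
    stop_invalid("fractions were computed on a different grid")
  img <- compose_activity(fractions, activity)
  img <- blur(img, acq$psf_fwhm)
  if (acq$extra_blur_fwhm > 0) img <- blur(img, rep(acq$extra_blur_fwhm, 3))
  if (acq$modality == "spect-like") img <- concentration_to_counts(img, acq)
  noise <- acq$noise
  if (!is.null(seed)) noise$seed <- seed
  img <- add_noise(img, noise)
  img$provenance <- sprintf("%s sbr=%s seed=%s", acq$modality,
                            format(activity$sbr), format(seed %||% NA))
  img
}
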