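# Calibration, recovery coefficients, threshold sweeps, best-threshold
# selection and volume estimation.

#' Sensitivity factor from a uniform-phantom count image
#'
#' Mean counts per voxel in a central cylindrical ROI (default 100 mm
#' diameter x 60 mm length), converted to cps per MBq per voxel:
#' `factor = (mean counts / duration) / (concentration_MBq_per_mL x voxel
#' volume mL)`.
#'
#' @param uniform_image counts image of the uniformly filled phantom
#'   (no spheres, no lung insert).
#' @param true_concentration_MBqml true activity concentration, MBq/mL.
#' @param duration_s effective acquisition time per voxel, seconds.
#' @param roi_diameter_mm,roi_length_mm ROI cylinder dimensions.
#' @return list with `sensitivity_factor` (cps/MBq voxel) and `n_voxels`.
#' @export
sensitivity_factor <- function(uniform_image, true_concentration_MBqml,
                               duration_s, roi_diameter_mm = 100,
                               roi_length_mm = 60) {
  if (uniform_image$value_unit != "counts")
    stop_invalid("uniform_image must be in counts")
  if (true_concentration_MBqml <= 0)
    stop_invalid("true concentration must be > 0")
  grid <- uniform_image$grid
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2)
  zs <- axis_coords(grid, 3)
  in_roi_xy <- outer(xs^2, ys^2, `+`) <= (roi_diameter_mm / 2)^2
  iz <- which(abs(zs) <= roi_length_mm / 2)
  if (!any(in_roi_xy) || !length(iz)) stop_coverage("ROI outside grid")
  sel <- uniform_image$values[, , iz][rep(in_roi_xy, times = length(iz))]
  mean_counts <- mean(sel)
  vox_ml <- voxel_volume_cm3(grid)
  structure(list(sensitivity_factor =
                   (mean_counts / duration_s) /
                   (true_concentration_MBqml * vox_ml),
                 mean_counts_per_voxel = mean_counts,
                 n_voxels = sum(in_roi_xy) * length(iz)),
            class = "calibration_result")
}

#' Convert a counts image to activity concentration
#'
#' Inverse of the SPECT-like calibration:
#' `kBq/mL = 1000 x (counts / duration) / (factor x voxel volume mL)`.
#'
#' @param image counts image.
#' @param cal a [sensitivity_factor()] result (or a bare cps/MBq-voxel
#'   number).
#' @param duration_s effective acquisition time per voxel, seconds.
#' @export
counts_to_concentration <- function(image, cal, duration_s) {
  if (image$value_unit != "counts")
    stop_invalid("image must be in counts")
  f <- if (inherits(cal, "calibration_result")) cal$sensitivity_factor
  else as.numeric(cal)
  if (!is.finite(f) || f <= 0) stop_invalid("sensitivity factor must be > 0")
  vox_ml <- voxel_volume_cm3(image$grid)
  image_volume(image$values / duration_s / (f * vox_ml) * 1000, image$grid,
               value_unit = "kBq/mL", provenance = image$provenance)
}

#' Quantify an image over a VOI
#'
#' @param image an [image_volume()] (typically kBq/mL).
#' @param mask a `voi_mask` (or logical array on the same grid).
#' @return list with `AC_max`, `AC_mean`, `volume_cm3`, `n_voxels`.
#' @export
quantify <- function(image, mask) {
  m <- if (inherits(mask, "voi_mask")) mask$mask else mask
  if (!any(m)) stop_infeasible("empty mask")
  vals <- image$values[m]
  list(AC_max = max(vals), AC_mean = mean(vals),
       volume_cm3 = sum(m) * voxel_volume_cm3(image$grid),
       n_voxels = sum(m))
}

#' Recovery coefficient
#'
#' @param measured measured quantity (concentration or volume).
#' @param true true quantity in the same unit; must be positive.
#' @return `measured / true`.
#' @export
recovery_coefficient <- function(measured, true) {
  if (any(true <= 0)) stop_invalid("true value must be > 0")
  measured / true
}

#' Threshold sweep over spheres
#'
#' One row per sphere x threshold fraction: segmentation (given method),
#' quantification, and recovery coefficients against the simulation truth.
#' Infeasible combinations are kept as rows with `feasible = FALSE` and NA
#' measurements; they are never dropped.
#'
#' @param image concentration image (kBq/mL).
#' @param geom phantom geometry.
#' @param activity the [activity_config()] the image was simulated with
#'   (source of the true concentration).
#' @param method `"threshold"` or `"adapted"` (the CT method takes no
#'   threshold; see [recovery_curve()]).
#' @param T_grid threshold fractions, default `seq(0.1, 0.9, by = 0.1)`.
#' @param sphere_ids spheres to process (default all).
#' @param seed replicate label carried into the table (not used for RNG).
#' @return A `data.frame` (class `sweep_table`).
#' @export
sweep_thresholds <- function(image, geom, activity,
                             method = c("threshold", "adapted"),
                             T_grid = seq(0.1, 0.9, by = 0.1),
                             sphere_ids = names(geom$spheres),
                             seed = NA_integer_) {
  method <- match.arg(method)
  if (any(T_grid <= 0 | T_grid >= 1))
    stop_invalid("T_grid must lie in (0, 1)")
  bg <- if (method == "adapted") estimate_background(image, geom) else NULL
  rows <- list()
  for (sid in sphere_ids) {
    s <- geom$spheres[[sid]]
    for (T in T_grid) {
      res <- segment(image, geom, sid, method, T = T, background = bg)
      if (is_feasible(res)) {
        q <- quantify(image, res)
        rows[[length(rows) + 1L]] <- data.frame(
          sphere_id = sid, diameter_mm = s$inner_diameter_mm,
          method = method, T = T, sbr = activity$sbr, seed = seed,
          feasible = TRUE,
          AC_max = q$AC_max, AC_mean = q$AC_mean,
          volume_cm3 = q$volume_cm3,
          true_volume_cm3 = s$true_volume_cm3,
          RC_max = recovery_coefficient(q$AC_max, activity$sphere_kBqml),
          RC_mean = recovery_coefficient(q$AC_mean, activity$sphere_kBqml),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          sphere_id = sid, diameter_mm = s$inner_diameter_mm,
          method = method, T = T, sbr = activity$sbr, seed = seed,
          feasible = FALSE,
          AC_max = NA_real_, AC_mean = NA_real_, volume_cm3 = NA_real_,
          true_volume_cm3 = s$true_volume_cm3,
          RC_max = NA_real_, RC_mean = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Best threshold from a sweep table
#'
#' Concentration criterion: per (method, SBR), the T minimising the median
#' over feasible spheres of `|RC_mean - 1|` — a robust reading of "best for
#' the majority of the spheres". Volume criterion: per sphere, the T
#' minimising `|volume - true volume|`. Ties go to the lower T.
#'
#' @param table a [sweep_thresholds()] result (rows may mix spheres and
#'   seeds; they are aggregated by mean score per T).
#' @param criterion `"concentration"` or `"volume"`.
#' @return `data.frame` with the selected `T_star` (one row per
#'   method x sbr, or per method x sbr x sphere for the volume criterion).
#' @export
select_best_threshold <- function(table,
                                  criterion = c("concentration", "volume")) {
  criterion <- match.arg(criterion)
  tab <- table[table$feasible, , drop = FALSE]
  if (!nrow(tab)) stop_infeasible("no feasible rows in sweep table")
  if (criterion == "concentration") {
    sp <- split(tab, list(tab$method, tab$sbr), drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(g) {
      score <- vapply(split(g, g$T), function(h)
        stats::median(abs(h$RC_mean - 1)), numeric(1))
      Ts <- as.numeric(names(score))
      best <- Ts[score <= min(score) + 1e-12]
      data.frame(method = g$method[1], sbr = g$sbr[1], T_star = min(best),
                 score = min(score), stringsAsFactors = FALSE)
    }))
  } else {
    sp <- split(tab, list(tab$method, tab$sbr, tab$sphere_id), drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(g) {
      score <- vapply(split(g, g$T), function(h)
        mean(abs(h$volume_cm3 - h$true_volume_cm3)), numeric(1))
      Ts <- as.numeric(names(score))
      best <- Ts[score <= min(score) + 1e-12]
      data.frame(method = g$method[1], sbr = g$sbr[1],
                 sphere_id = g$sphere_id[1],
                 diameter_mm = g$diameter_mm[1], T_star = min(best),
                 score = min(score), stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Recovery curve
#'
#' Per-sphere recovery coefficients ordered by diameter: for threshold
#' methods at a chosen T (e.g. the [select_best_threshold()] winner), or
#' for the CT method / max-in-region method which take no threshold.
#'
#' @param image concentration image.
#' @param geom phantom geometry.
#' @param activity the simulation's [activity_config()] (truth).
#' @param method `"threshold"`, `"adapted"`, `"ct"`, `"ct3d"` or `"max"`
#'   (`"max"` = AC_max in the search region, no VOI).
#' @param statistic `"mean"` or `"max"` in-VOI statistic.
#' @param T threshold fraction for threshold methods.
#' @return `data.frame` sorted ascending by diameter with columns
#'   `sphere_id`, `diameter_mm`, `RC`, `feasible`.
#' @export
recovery_curve <- function(image, geom, activity,
                           method = c("ct", "ct3d", "threshold", "adapted",
                                      "max"),
                           statistic = c("mean", "max"), T = NULL) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  rows <- lapply(geom$spheres, function(s) {
    rc <- NA_real_; feas <- FALSE
    if (method == "max") {
      mx <- find_max(image, search_region(geom, image$grid, s$id))
      rc <- recovery_coefficient(mx$AC_max, activity$sphere_kBqml)
      feas <- TRUE
    } else {
      res <- segment(image, geom, s$id, method, T = T)
      if (is_feasible(res)) {
        q <- quantify(image, res)
        v <- if (statistic == "mean") q$AC_mean else q$AC_max
        rc <- recovery_coefficient(v, activity$sphere_kBqml)
        feas <- TRUE
      }
    }
    data.frame(sphere_id = s$id, diameter_mm = s$inner_diameter_mm,
               RC = rc, feasible = feas, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$diameter_mm), ]
  rownames(out) <- NULL
  out
}
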