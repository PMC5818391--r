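# VOI definition: fixed-fraction thresholds, background-adapted thresholds
# (T_adapt = T * (AC_max - BG) + BG), and CT-based reference ROIs, with
# 26-connected region growing from the maximum voxel.

#' Search region around a sphere
#'
#' A cube of side `2 x inner diameter` centered on the nominal sphere
#' center, clipped to the grid: large enough never to clip a correct VOI,
#' small enough to stop threshold VOIs flooding the whole background at low
#' sphere-to-background ratios.
#'
#' @param geom phantom geometry.
#' @param grid a [grid_spec()].
#' @param sphere_id sphere label (see [default_nema_geometry()]).
#' @return list of index ranges `ix`, `iy`, `iz` (1-based).
#' @export
search_region <- function(geom, grid, sphere_id) {
  s <- geom$spheres[[sphere_id]]
  if (is.null(s)) stop_invalid(sprintf("unknown sphere '%s'", sphere_id))
  half <- s$inner_diameter_mm  # half-side = diameter
  r <- lapply(1:3, function(ax)
    index_range(grid, ax, s$center[ax] - half, s$center[ax] + half))
  if (any(lengths(r) == 0)) stop_coverage("search region outside grid")
  names(r) <- c("ix", "iy", "iz")
  r
}

#' Maximum value in a search region
#'
#' @param image an [image_volume()].
#' @param region a [search_region()] (list of index ranges).
#' @return list with `AC_max` and `location` (length-3 voxel index).
#' @export
find_max <- function(image, region) {
  if (any(lengths(region) == 0)) stop_invalid("empty search region")
  sub <- image$values[region$ix, region$iy, region$iz, drop = FALSE]
  k <- which.max(sub)
  loc <- arrayInd(k, dim(sub))
  structure(list(AC_max = sub[k],
                 location = c(region$ix[loc[1]], region$iy[loc[2]],
                              region$iz[loc[3]])),
            class = "max_estimate")
}

#' Background estimate from three fixed ROIs
#'
#' Three cubic ROIs (default 15 mm side) placed deterministically in the
#' background at 120-degree spacing in the sphere plane, midway between the
#' sphere circle and the phantom edge, each at least `clearance_mm` from
#' every sphere surface, the lung insert and the body wall. BG is the mean
#' of the three ROI means.
#'
#' @param image an [image_volume()].
#' @param geom phantom geometry.
#' @param roi_side_mm ROI edge length in mm.
#' @param roi_radius_mm distance of ROI centers from the phantom axis.
#' @param clearance_mm minimum clearance to spheres/lung/wall.
#' @return list with `BG`, `roi_means`, `roi_centers`.
#' @export
estimate_background <- function(image, geom, roi_side_mm = 15,
                                roi_radius_mm = 90, clearance_mm = 15) {
  grid <- image$grid
  # offset 30 degrees from the first sphere, then every 120 degrees
  base_ang <- if (length(geom$spheres))
    atan2(geom$spheres[[1]]$center[2], geom$spheres[[1]]$center[1]) else 0
  angles <- base_ang + (pi / 6) + (0:2) * (2 * pi / 3)
  zc <- if (length(geom$spheres)) geom$spheres[[1]]$center[3] else 0
  centers <- lapply(angles, function(a)
    c(roi_radius_mm * cos(a), roi_radius_mm * sin(a), zc))
  half <- roi_side_mm / 2
  b <- geom$body
  # distance from an axis-aligned box (center ctr, half-side half) to a point
  box_point_dist <- function(ctr, p)
    sqrt(sum(pmax(abs(p - ctr) - half, 0)^2))
  corners <- as.matrix(expand.grid(c(-half, half), c(-half, half)))
  roi_means <- vapply(centers, function(ctr) {
    # containment checks: inside body with clearance, clear of compartments
    wall <- min(-stadium_sd(ctr[1] + corners[, 1], ctr[2] + corners[, 2],
                            b$width_mm, b$height_mm))
    if (wall < clearance_mm ||
        abs(ctr[3]) + half + clearance_mm > b$length_mm / 2)
      stop_geometry("background ROI too close to the body wall")
    if (!is.null(geom$lung)) {
      d2 <- sqrt(sum(pmax(abs(geom$lung$center_xy - ctr[1:2]) - half, 0)^2))
      if (d2 < geom$lung$radius_mm + clearance_mm)
        stop_geometry("background ROI too close to the lung insert")
    }
    for (s in geom$spheres) {
      if (box_point_dist(ctr, s$center) < s$radius_mm + clearance_mm)
        stop_geometry("background ROI too close to a sphere")
    }
    rng <- lapply(1:3, function(ax)
      index_range(grid, ax, ctr[ax] - half, ctr[ax] + half))
    if (any(lengths(rng) == 0)) stop_coverage("background ROI outside grid")
    mean(image$values[rng[[1]], rng[[2]], rng[[3]]])
  }, numeric(1))
  # noise can push the estimate below zero on cold backgrounds; activity
  # concentration is nonnegative, so the estimate is floored at 0
  structure(list(BG = max(0, mean(roi_means)), roi_means = roi_means,
                 roi_centers = centers, roi_side_mm = roi_side_mm),
            class = "background_estimate")
}

#' Background-adapted absolute threshold
#'
#' `T_adapt = T * (AC_max - BG) + BG`: interpolates between the background
#' level and the lesion maximum. With BG = 0 it reduces to the plain
#' fractional threshold; with T = 1 it equals AC_max.
#'
#' @param T threshold fraction in (0, 1].
#' @param AC_max measured maximum (a [find_max()] result or a number).
#' @param BG background level (an [estimate_background()] result or a
#'   number).
#' @return Absolute threshold level in image units.
#' @export
adapted_threshold <- function(T, AC_max, BG) {
  if (inherits(AC_max, "max_estimate")) AC_max <- AC_max$AC_max
  if (inherits(BG, "background_estimate")) BG <- BG$BG
  check_threshold_fraction(T)
  if (BG < 0) stop_invalid("BG must be >= 0")
  if (AC_max < BG)
    stop_infeasible("AC_max below background: sphere not segmentable")
  T * (AC_max - BG) + BG
}

#' Plain fractional threshold
#'
#' @inheritParams adapted_threshold
#' @return `T * AC_max` in image units.
#' @export
plain_threshold <- function(T, AC_max) {
  if (inherits(AC_max, "max_estimate")) AC_max <- AC_max$AC_max
  check_threshold_fraction(T)
  if (AC_max <= 0)
    stop_infeasible("nonpositive maximum: sphere not segmentable")
  T * AC_max
}

check_threshold_fraction <- function(T) {
  if (!is.finite(T) || T <= 0 || T > 1)
    stop_invalid("threshold fraction T must be in (0, 1]")
  invisible(T)
}

#' Grow a VOI by 26-connected thresholding
#'
#' The 26-connected component of voxels with value >= `level` within the
#' search region, grown from `seed_location` (normally the AC_max voxel).
#'
#' @param image an [image_volume()].
#' @param level absolute threshold in image units.
#' @param seed_location length-3 voxel index; its value must be >= level.
#' @param region a [search_region()] index-range list.
#' @return Logical 3-D array over the full grid (attribute-free); see
#'   [segment()] for the provenance-carrying wrapper.
#' @export
grow_voi <- function(image, level, seed_location, region) {
  vals <- image$values
  if (vals[seed_location[1], seed_location[2], seed_location[3]] < level)
    stop_infeasible("seed voxel below threshold level: empty VOI")
  if (!(seed_location[1] %in% region$ix && seed_location[2] %in% region$iy &&
        seed_location[3] %in% region$iz))
    stop_invalid("seed location outside search region")
  sub <- vals[region$ix, region$iy, region$iz, drop = FALSE] >= level
  d <- dim(sub)
  # pad with FALSE so neighbour offsets never wrap
  pd <- d + 2L
  padded <- array(FALSE, pd)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- sub
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  lin_offs <- offs[, 1] + pd[1] * offs[, 2] + pd[1] * pd[2] * offs[, 3]
  seed_sub <- c(match(seed_location[1], region$ix) + 1L,
                match(seed_location[2], region$iy) + 1L,
                match(seed_location[3], region$iz) + 1L)
  seed_lin <- seed_sub[1] + pd[1] * (seed_sub[2] - 1L) +
    pd[1] * pd[2] * (seed_sub[3] - 1L)
  visited <- array(FALSE, pd)
  visited[seed_lin] <- TRUE
  frontier <- seed_lin
  while (length(frontier)) {
    cand <- unique(as.vector(outer(frontier, lin_offs, `+`)))
    cand <- cand[padded[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  comp <- visited[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
  mask <- array(FALSE, image$grid$dims)
  mask[region$ix, region$iy, region$iz] <- comp
  mask
}

# Does the component touch the boundary of its search region? A VOI that
# reaches the region edge has flooded into the background and is treated
# as a failed segmentation.
touches_region_boundary <- function(mask, region) {
  sub <- mask[region$ix, region$iy, region$iz, drop = FALSE]
  d <- dim(sub)
  any(sub[1, , ]) || any(sub[d[1], , ]) ||
    any(sub[, 1, ]) || any(sub[, d[2], ]) ||
    any(sub[, , 1]) || any(sub[, , d[3]])
}

voi_mask <- function(mask, grid, method, sphere_id, T = NA_real_,
                     level = NA_real_) {
  structure(list(mask = mask, grid = grid, method = method,
                 sphere_id = sphere_id, T = T, absolute_level = level,
                 n_voxels = sum(mask)),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("voi_mask [%s] %s: %d voxels (%.2f cm^3)%s\n", x$method,
              x$sphere_id, x$n_voxels,
              x$n_voxels * voxel_volume_cm3(x$grid),
              if (is.na(x$T)) "" else sprintf(", T = %.2f", x$T)))
  invisible(x)
}

#' CT-based reference ROI for a sphere
#'
#' Emulates an ROI drawn on CT at the sphere's inside border in the slice
#' through the sphere center and copied into the emission image: a
#' single-slice disk of voxels whose in-plane center lies within the inner
#' radius. When the sphere center falls midway between two slices the lower
#' slice index is used. If no voxel center falls inside the disk (small
#' sphere on a coarse grid) the mask degenerates to the single voxel
#' containing the center.
#'
#' @param geom phantom geometry.
#' @param grid a [grid_spec()].
#' @param sphere_id sphere label.
#' @param three_d if TRUE, return the full 3-D sphere mask instead (method
#'   label `"ct3d"`); off by default.
#' @return A `voi_mask`.
#' @export
ct_reference_mask <- function(geom, grid, sphere_id, three_d = FALSE) {
  s <- geom$spheres[[sphere_id]]
  if (is.null(s)) stop_invalid(sprintf("unknown sphere '%s'", sphere_id))
  ctr_idx <- vapply(1:3, function(ax) nearest_index(grid, ax, s$center[ax]),
                    integer(1))
  if (any(ctr_idx < 1L) || any(ctr_idx > grid$dims))
    stop_coverage("sphere center outside grid")
  mask <- array(FALSE, grid$dims)
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2)
  if (three_d) {
    zs <- axis_coords(grid, 3)
    for (iz in index_range(grid, 3, s$center[3] - s$radius_mm,
                           s$center[3] + s$radius_mm)) {
      rz2 <- s$radius_mm^2 - (zs[iz] - s$center[3])^2
      if (rz2 < 0) next
      d2 <- outer((xs - s$center[1])^2, (ys - s$center[2])^2, `+`)
      mask[, , iz] <- d2 <= rz2
    }
    if (!any(mask)) mask[ctr_idx[1], ctr_idx[2], ctr_idx[3]] <- TRUE
    return(voi_mask(mask, grid, "ct3d", sphere_id))
  }
  iz <- ctr_idx[3]
  d2 <- outer((xs - s$center[1])^2, (ys - s$center[2])^2, `+`)
  mask[, , iz] <- d2 <= s$radius_mm^2
  if (!any(mask)) mask[ctr_idx[1], ctr_idx[2], iz] <- TRUE
  voi_mask(mask, grid, "ct", sphere_id)
}

#' Segment one sphere in an image
#'
#' Dispatches the three VOI-definition methods: `"threshold"` (level =
#' `T x AC_max`), `"adapted"` (level = `T x (AC_max - BG) + BG`, Eq.-1-style
#' background adaptation) and `"ct"` (geometry-derived single-slice ROI).
#' AC_max is taken within the search region before growth; the grown
#' component must stay off the search-region boundary, otherwise the
#' segmentation is reported infeasible (it has flooded into background).
#'
#' @param image an [image_volume()].
#' @param geom phantom geometry.
#' @param sphere_id sphere label.
#' @param method `"threshold"`, `"adapted"`, `"ct"` or `"ct3d"`.
#' @param T threshold fraction for the threshold methods.
#' @param background optional precomputed [estimate_background()] (adapted
#'   method only; computed on the fly when missing).
#' @return A `voi_mask`, or an object of class `infeasible_segmentation`
#'   (with `$reason`) when the sphere cannot be segmented — infeasibility
#'   is a first-class result, not an error.
#' @export
segment <- function(image, geom, sphere_id,
                    method = c("threshold", "adapted", "ct", "ct3d"),
                    T = NULL, background = NULL) {
  method <- match.arg(method)
  if (method %in% c("ct", "ct3d"))
    return(ct_reference_mask(geom, image$grid, sphere_id,
                             three_d = method == "ct3d"))
  if (is.null(T)) stop_invalid("threshold methods need T")
  region <- search_region(geom, image$grid, sphere_id)
  mx <- find_max(image, region)
  res <- tryCatch({
    level <- if (method == "adapted") {
      bg <- background %||% estimate_background(image, geom)
      adapted_threshold(T, mx, bg)
    } else {
      plain_threshold(T, mx)
    }
    mask <- grow_voi(image, level, mx$location, region)
    if (touches_region_boundary(mask, region))
      stop_infeasible("VOI reached the search-region boundary")
    voi_mask(mask, image$grid, method, sphere_id, T = T, level = level)
  }, nemaquant_infeasible = function(e) {
    structure(list(sphere_id = sphere_id, method = method, T = T,
                   reason = conditionMessage(e)),
              class = "infeasible_segmentation")
  })
  res
}

#' @export
print.infeasible_segmentation <- function(x, ...) {
  cat(sprintf("infeasible segmentation [%s] %s (T = %s): %s\n", x$method,
              x$sphere_id, format(x$T), x$reason))
  invisible(x)
}

#' Is a segmentation result feasible?
#'
#' @param x result of [segment()].
#' @export
is_feasible <- function(x) inherits(x, "voi_mask")
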