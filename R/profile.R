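# Line profiles (trilinear interpolation) and a contrast-to-noise
# detectability score.

# Trilinear interpolation of the image at world points (matrix n x 3, mm).
interp_trilinear <- function(image, pts) {
  grid <- image$grid
  g <- sweep(sweep(pts, 2, grid$origin, `-`), 2, grid$spacing, `/`)  # 0-based
  i0 <- floor(g)
  f <- g - i0
  vals <- numeric(nrow(pts))
  v <- image$values
  dims <- grid$dims
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    ix <- i0[, 1] + c1 + 1L; iy <- i0[, 2] + c2 + 1L; iz <- i0[, 3] + c3 + 1L
    if (any(ix < 1L | ix > dims[1] | iy < 1L | iy > dims[2] |
            iz < 1L | iz > dims[3]))
      stop_coverage("profile endpoints outside grid")
    w <- (c1 * f[, 1] + (1 - c1) * (1 - f[, 1])) *
      (c2 * f[, 2] + (1 - c2) * (1 - f[, 2])) *
      (c3 * f[, 3] + (1 - c3) * (1 - f[, 3]))
    vals <- vals + w * v[cbind(ix, iy, iz)]
  }
  vals
}

#' Line profile through an image
#'
#' Trilinear interpolation along the segment from `start` to `end` at the
#' given step. Both endpoints must lie inside the interpolable interior of
#' the grid.
#'
#' @param image an [image_volume()].
#' @param start,end world coordinates (mm), length 3.
#' @param step_mm sample spacing along the segment; default half the
#'   smallest voxel dimension.
#' @return A `line_profile`: `data.frame` with `position_mm` (distance from
#'   `start`) and `value`, plus endpoint attributes.
#' @export
line_profile <- function(image, start, end,
                         step_mm = min(image$grid$spacing) / 2) {
  if (step_mm <= 0) stop_invalid("step must be > 0")
  start <- as.numeric(start); end <- as.numeric(end)
  len <- sqrt(sum((end - start)^2))
  pos <- seq(0, len, by = step_mm)
  if (pos[length(pos)] < len) pos <- c(pos, len)
  dirv <- if (len > 0) (end - start) / len else c(0, 0, 0)
  pts <- outer(pos, dirv) + matrix(start, length(pos), 3, byrow = TRUE)
  vals <- interp_trilinear(image, pts)
  out <- data.frame(position_mm = pos, value = vals)
  attr(out, "start") <- start
  attr(out, "end") <- end
  class(out) <- c("line_profile", "data.frame")
  out
}

#' Peak contrast-to-noise score of a profile
#'
#' `(peak - BG) / noise_sd`, a Rose-criterion-style numeric stand-in for
#' visual detectability; a sphere is flagged detectable when the score
#' reaches `threshold` (default 4). This is a convenience metric, not a
#' calibrated human-observer model.
#'
#' @param profile a [line_profile()].
#' @param background an [estimate_background()] result or a number.
#' @param noise_sd image noise standard deviation (same units).
#' @param threshold detectability cut on the score.
#' @return list with `score`, `peak`, `detectable`.
#' @export
peak_contrast <- function(profile, background, noise_sd, threshold = 4) {
  if (noise_sd <= 0) stop_invalid("noise_sd must be > 0")
  bg <- if (inherits(background, "background_estimate")) background$BG
  else as.numeric(background)
  peak <- max(profile$value)
  score <- (peak - bg) / noise_sd
  list(score = score, peak = peak, detectable = score >= threshold)
}

#' Default detectability profile endpoints
#'
#' The segment through the centers of the 37- and 17-mm spheres in the
#' sphere plane, extended by `margin_mm` beyond each center.
#'
#' @param geom phantom geometry.
#' @param margin_mm extension beyond each sphere center, mm.
#' @return list with `start` and `end` (mm).
#' @export
default_profile_endpoints <- function(geom, margin_mm = 30) {
  ids <- names(geom$spheres)
  d <- vapply(geom$spheres, `[[`, numeric(1), "inner_diameter_mm")
  c37 <- geom$spheres[[ids[which.min(abs(d - 37))]]]$center
  c17 <- geom$spheres[[ids[which.min(abs(d - 17))]]]$center
  u <- (c17 - c37) / sqrt(sum((c17 - c37)^2))
  list(start = c37 - margin_mm * u, end = c17 + margin_mm * u)
}
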