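#' Image grid specification
#'
#' Describes a regular 3-D voxel grid in world (phantom) coordinates.
#' Coordinates are right-handed, in millimetres; voxel indices are 1-based in
#' R but a voxel's world coordinate is the coordinate of its *center*; axial
#' slices are constant-z planes.
#'
#' @param dims integer length-3, number of voxels along x, y, z.
#' @param spacing numeric length-3, voxel spacing in mm (dx, dy, dz).
#' @param origin numeric length-3, world coordinate (mm) of the center of
#'   voxel (1,1,1). Default centers the grid on the world origin.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(dims, spacing, origin = NULL) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  if (length(dims) != 3L || any(dims < 1L))
    stop_invalid("dims must be three positive integers")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_invalid("spacing must be three positive numbers (mm)")
  if (is.null(origin)) origin <- -spacing * (dims - 1) / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop_invalid("origin must be length 3 (mm)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, voxel volume %.4f cm^3\n",
              x$origin[1], x$origin[2], x$origin[3], voxel_volume_cm3(x)))
  invisible(x)
}

#' Voxel volume in cubic centimetres
#'
#' @param grid a [grid_spec()].
#' @return Voxel volume in cm^3.
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

# World coordinates of voxel centers along one axis (1..n).
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

# Voxel index (1-based, per axis) whose center is nearest to world
# coordinate w on the given axis. Ties (w exactly midway) round to the
# lower index.
nearest_index <- function(grid, axis, w) {
  i <- floor((w - grid$origin[axis]) / grid$spacing[axis] + 0.5)
  # floor(x + 0.5) rounds half-way cases up; pull exact ties back down
  frac <- (w - grid$origin[axis]) / grid$spacing[axis]
  if (isTRUE(all.equal(frac %% 1, 0.5))) i <- floor(frac)
  as.integer(i) + 1L
}

# Does the grid's extent (outer voxel faces) contain the axis-aligned box
# [lo, hi] (mm)?
grid_covers_box <- function(grid, lo, hi) {
  gmin <- grid$origin - grid$spacing / 2
  gmax <- grid$origin + (grid$dims - 1) * grid$spacing + grid$spacing / 2
  all(lo >= gmin - 1e-9) && all(hi <= gmax + 1e-9)
}

# Clamped range of indices whose voxel centers lie in [lo, hi] (mm).
index_range <- function(grid, axis, lo, hi) {
  sp <- grid$spacing[axis]; o <- grid$origin[axis]
  i0 <- max(1L, as.integer(ceiling((lo - o) / sp - 1e-9)) + 1L)
  i1 <- min(grid$dims[axis], as.integer(floor((hi - o) / sp + 1e-9)) + 1L)
  if (i0 > i1) integer(0) else i0:i1
}
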