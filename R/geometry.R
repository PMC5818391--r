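#' Volume of a sphere from its diameter
#'
#' @param diameter_mm sphere inner diameter in mm.
#' @return Volume in cm^3, `(pi/6) * (d/10)^3`.
#' @examples
#' sphere_volume(37)  # 26.52 cm^3
#' sphere_volume(10)  # 0.52 cm^3
#' @export
sphere_volume <- function(diameter_mm) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0))
    stop_invalid("diameter must be a positive number (mm)")
  (pi / 6) * (diameter_mm / 10)^3
}

#' Sphere specification
#'
#' @param id character label.
#' @param inner_diameter_mm inner diameter in mm.
#' @param center numeric length-3, center (x, y, z) in mm, phantom frame.
#' @return A `sphere_spec` list with the analytic `true_volume_cm3`.
#' @export
sphere_spec <- function(id, inner_diameter_mm, center) {
  if (inner_diameter_mm <= 0) stop_invalid("inner_diameter must be > 0")
  structure(list(id = as.character(id),
                 inner_diameter_mm = inner_diameter_mm,
                 radius_mm = inner_diameter_mm / 2,
                 center = as.numeric(center),
                 true_volume_cm3 = sphere_volume(inner_diameter_mm)),
            class = "sphere_spec")
}

#' Cylindrical insert specification
#'
#' The axis is parallel to z through `center_xy`; the cylinder spans
#' `length_mm` symmetrically about z = 0.
#'
#' @param outer_diameter_mm outer diameter in mm (51 for the standard lung
#'   insert).
#' @param length_mm axial length in mm.
#' @param center_xy in-plane axis position (mm), default phantom center.
#' @export
cylinder_spec <- function(outer_diameter_mm = 51, length_mm = 180,
                          center_xy = c(0, 0)) {
  if (outer_diameter_mm <= 0 || length_mm <= 0)
    stop_invalid("cylinder dimensions must be positive")
  structure(list(outer_diameter_mm = outer_diameter_mm,
                 radius_mm = outer_diameter_mm / 2,
                 length_mm = length_mm,
                 center_xy = as.numeric(center_xy)),
            class = "cylinder_spec")
}

# Signed distance (mm) to the body cross-section boundary: a stadium
# (rounded rectangle) of overall extent width_mm x height_mm, i.e. two
# half-discs of radius height/2 joined by a straight section. Negative
# inside.
stadium_sd <- function(x, y, width_mm, height_mm) {
  r <- height_mm / 2
  a <- width_mm / 2 - r  # half-length of the straight section
  sqrt(pmax(abs(x) - a, 0)^2 + y^2) - r
}

#' NEMA IEC body phantom geometry
#'
#' Builds the analytic phantom: six fillable spheres (inner diameters 10,
#' 13, 17, 22, 28, 37 mm by default) with centers coplanar on a circle of
#' 114.4 mm diameter in the transaxial plane z = 0; a 51-mm cylindrical
#' lung insert on the phantom axis; and a torso-like body outline
#' approximated as a 300 x 230 mm stadium cross-section extruded 180 mm in
#' z. Compartments are `outside`, `background` (body minus spheres minus
#' lung), `lung`, and one per sphere.
#'
#' @param sphere_diameters_mm inner diameters in mm, largest placed at
#'   angle `angle0_deg` and the rest every 60 degrees counter-clockwise.
#' @param sphere_circle_diameter_mm diameter of the circle carrying the
#'   sphere centers.
#' @param sphere_plane_z z position (mm) of the common sphere plane.
#' @param body_width_mm,body_height_mm,body_length_mm body outline extents.
#' @param lung_diameter_mm outer diameter of the lung insert.
#' @param angle0_deg angle of the first (largest) sphere, degrees from +x.
#' @return A `phantom_geometry` object.
#' @export
default_nema_geometry <- function(sphere_diameters_mm = c(37, 28, 22, 17, 13, 10),
                                  sphere_circle_diameter_mm = 114.4,
                                  sphere_plane_z = 0,
                                  body_width_mm = 300,
                                  body_height_mm = 230,
                                  body_length_mm = 180,
                                  lung_diameter_mm = 51,
                                  angle0_deg = 0) {
  rc <- sphere_circle_diameter_mm / 2
  ang <- (angle0_deg + 60 * (seq_along(sphere_diameters_mm) - 1)) * pi / 180
  spheres <- lapply(seq_along(sphere_diameters_mm), function(i) {
    d <- sphere_diameters_mm[i]
    sphere_spec(id = sprintf("sphere_%02.0fmm", d),
                inner_diameter_mm = d,
                center = c(rc * cos(ang[i]), rc * sin(ang[i]), sphere_plane_z))
  })
  names(spheres) <- vapply(spheres, `[[`, "", "id")
  geom <- structure(list(spheres = spheres,
                         lung = cylinder_spec(lung_diameter_mm,
                                              length_mm = body_length_mm),
                         body = list(width_mm = body_width_mm,
                                     height_mm = body_height_mm,
                                     length_mm = body_length_mm)),
                    class = "phantom_geometry")
  validate_geometry(geom)
  geom
}

#' Uniform phantom (no spheres, no lung insert) for calibration scans
#'
#' @inheritParams default_nema_geometry
#' @export
uniform_phantom_geometry <- function(body_width_mm = 300, body_height_mm = 230,
                                     body_length_mm = 180) {
  structure(list(spheres = list(),
                 lung = NULL,
                 body = list(width_mm = body_width_mm,
                             height_mm = body_height_mm,
                             length_mm = body_length_mm)),
            class = "phantom_geometry")
}

# Invariants: spheres inside the body, clear of the lung insert, pairwise
# disjoint; sphere volume consistent with the analytic formula.
validate_geometry <- function(geom) {
  b <- geom$body
  for (s in geom$spheres) {
    sd_body <- stadium_sd(s$center[1], s$center[2], b$width_mm, b$height_mm)
    if (sd_body + s$radius_mm > 0 ||
        abs(s$center[3]) + s$radius_mm > b$length_mm / 2)
      stop_geometry(sprintf("%s extends outside the body outline", s$id))
    if (!is.null(geom$lung)) {
      d_lung <- sqrt(sum((s$center[1:2] - geom$lung$center_xy)^2))
      if (d_lung < s$radius_mm + geom$lung$radius_mm)
        stop_geometry(sprintf("%s intersects the lung insert", s$id))
    }
    v <- (pi / 6) * (s$inner_diameter_mm / 10)^3
    if (abs(s$true_volume_cm3 - v) / v > 0.005)
      stop_geometry(sprintf("%s volume inconsistent with its diameter", s$id))
  }
  ids <- names(geom$spheres)
  for (i in seq_along(geom$spheres)) {
    for (j in seq_len(i - 1L)) {
      si <- geom$spheres[[i]]; sj <- geom$spheres[[j]]
      if (sqrt(sum((si$center - sj$center)^2)) < si$radius_mm + sj$radius_mm)
        stop_geometry(sprintf("%s and %s overlap", ids[i], ids[j]))
    }
  }
  invisible(geom)
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("phantom_geometry: %d spheres, body %g x %g x %g mm%s\n",
              length(x$spheres), x$body$width_mm, x$body$height_mm,
              x$body$length_mm,
              if (is.null(x$lung)) ", no lung insert"
              else sprintf(", lung insert %g mm", x$lung$outer_diameter_mm)))
  for (s in x$spheres)
    cat(sprintf("  %s: d=%g mm, V=%.2f cm^3, center (%.1f, %.1f, %.1f) mm\n",
                s$id, s$inner_diameter_mm, s$true_volume_cm3,
                s$center[1], s$center[2], s$center[3]))
  invisible(x)
}

compartment_names <- function(geom) {
  c("outside", "background",
    if (!is.null(geom$lung)) "lung",
    names(geom$spheres))
}

# Point-membership tests (vectorized over points given as columns x, y, z).
inside_body <- function(geom, x, y, z) {
  b <- geom$body
  (stadium_sd(x, y, b$width_mm, b$height_mm) <= 0) & (abs(z) <= b$length_mm / 2)
}

inside_lung <- function(geom, x, y, z) {
  if (is.null(geom$lung)) return(rep(FALSE, length(x)))
  l <- geom$lung
  (sqrt((x - l$center_xy[1])^2 + (y - l$center_xy[2])^2) <= l$radius_mm) &
    (abs(z) <= l$length_mm / 2)
}

inside_sphere <- function(sph, x, y, z) {
  (x - sph$center[1])^2 + (y - sph$center[2])^2 + (z - sph$center[3])^2 <=
    sph$radius_mm^2
}

#' Serialize a phantom geometry to JSON
#'
#' All lengths are in millimetres; the unit is recorded in the file.
#'
#' @param geom a `phantom_geometry`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @export
geometry_to_json <- function(geom, path = NULL) {
  obj <- list(
    units = "mm",
    body = geom$body,
    lung = if (!is.null(geom$lung))
      list(outer_diameter_mm = geom$lung$outer_diameter_mm,
           length_mm = geom$lung$length_mm,
           center_xy = geom$lung$center_xy),
    spheres = lapply(unname(geom$spheres), function(s)
      list(id = s$id, inner_diameter_mm = s$inner_diameter_mm,
           center = s$center))
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a phantom geometry from JSON
#'
#' @param path file written by [geometry_to_json()].
#' @export
geometry_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  spheres <- lapply(seq_len(nrow(obj$spheres)), function(i)
    sphere_spec(obj$spheres$id[i], obj$spheres$inner_diameter_mm[i],
                unlist(obj$spheres$center[i])))
  names(spheres) <- vapply(spheres, `[[`, "", "id")
  lung <- if (!is.null(obj$lung))
    cylinder_spec(obj$lung$outer_diameter_mm, obj$lung$length_mm,
                  obj$lung$center_xy)
  geom <- structure(list(spheres = spheres, lung = lung,
                         body = as.list(obj$body)),
                    class = "phantom_geometry")
  validate_geometry(geom)
  geom
}
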