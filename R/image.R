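#' 3-D image volume
#'
#' A scalar voxel grid with spacing/origin metadata and a value-unit tag.
#'
#' @param values 3-D numeric array.
#' @param grid a [grid_spec()] matching `dim(values)`.
#' @param value_unit `"kBq/mL"` or `"counts"` (or `"fraction"` for masks
#'   and occupancy maps).
#' @param provenance free-text provenance (preset name, seed, ...).
#' @export
image_volume <- function(values, grid, value_unit = c("kBq/mL", "counts",
                                                      "fraction"),
                         provenance = "") {
  value_unit <- match.arg(value_unit)
  if (!identical(dim(values), NULL) && !all(dim(values) == grid$dims))
    stop_invalid("values dimensions do not match grid dims")
  if (is.null(dim(values))) stop_invalid("values must be a 3-D array")
  if (!all(is.finite(values))) stop_invalid("image values must be finite")
  structure(list(values = values, grid = grid, value_unit = value_unit,
                 provenance = provenance),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume [%s]: %d x %d x %d, range [%.4g, %.4g]\n",
              x$value_unit, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              min(x$values), max(x$values)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

same_grid <- function(a, b) {
  all(a$dims == b$dims) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9))
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 I/O (.nii, single file, little-endian, float32 or uint8,
# sform only). Implemented on writeBin/readBin because no NIfTI package is
# available in the target library; covers exactly what this package exports.
# ---------------------------------------------------------------------------

#' Write an image volume or mask as NIfTI-1
#'
#' Float32 for images and fraction maps, uint8 for masks. The affine (sform)
#' carries spacing and origin in mm; a sidecar JSON stores the value unit
#' and provenance.
#'
#' @param image an [image_volume()] or a `voi_mask`.
#' @param path output path ending in `.nii`.
#' @param sidecar write `<path>.json` with unit/provenance metadata.
#' @export
write_nifti <- function(image, path, sidecar = TRUE) {
  if (inherits(image, "voi_mask")) {
    vals <- array(as.integer(image$mask), dim = dim(image$mask))
    grid <- image$grid
    datatype <- 2L; bitpix <- 8L  # uint8
    meta <- list(kind = "mask", method = image$method,
                 sphere_id = image$sphere_id)
  } else if (inherits(image, "image_volume")) {
    vals <- image$values
    grid <- image$grid
    datatype <- 16L; bitpix <- 32L  # float32
    meta <- list(kind = "image", value_unit = image$value_unit,
                 provenance = image$provenance)
  } else stop_invalid("image must be an image_volume or voi_mask")

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), n))],
               raw(n - min(length(raw), n))), con)
  }
  # byte-offset-accurate NIfTI-1 header layout
  wi(348, 4)                                   # 0   sizeof_hdr
  wc("", 10)                                   # 4   data_type
  wc("", 18)                                   # 14  db_name
  wi(0, 4)                                     # 32  extents
  wi(0, 2)                                     # 36  session_error
  wc("r", 1)                                   # 38  regular
  wc("", 1)                                    # 39  dim_info
  wi(c(3, grid$dims, 1, 1, 1, 1), 2)           # 40  dim[8]
  wf(c(0, 0, 0))                               # 56  intent_p1..p3
  wi(0, 2)                                     # 68  intent_code
  wi(datatype, 2)                              # 70  datatype
  wi(bitpix, 2)                                # 72  bitpix
  wi(0, 2)                                     # 74  slice_start
  wf(c(1, grid$spacing, 0, 0, 0, 0))           # 76  pixdim[8] (qfac 1)
  wf(352)                                      # 108 vox_offset
  wf(1); wf(0)                                 # 112 scl_slope, scl_inter
  wi(0, 2); wc("", 1); wc("", 1)               # 120 slice_end, slice_code, xyzt_units
  wf(0); wf(0); wf(0)                          # 124 cal_max, cal_min, slice_duration
  wf(0)                                        # 136 toffset
  wi(0, 4); wi(0, 4)                           # 140 glmax, glmin
  wc("nemaquant", 80)                          # 148 descrip
  wc("", 24)                                   # 228 aux_file
  wi(0, 2); wi(1, 2)                           # 252 qform_code 0, sform_code 1
  wf(c(0, 0, 0, 0, 0, 0))                      # 256 quatern b,c,d, qoffset x,y,z
  wf(c(grid$spacing[1], 0, 0, grid$origin[1])) # 280 srow_x
  wf(c(0, grid$spacing[2], 0, grid$origin[2])) # 296 srow_y
  wf(c(0, 0, grid$spacing[3], grid$origin[3])) # 312 srow_z
  wc("", 16)                                   # 328 intent_name
  wc("n+1", 4)                                 # 344 magic
  writeBin(raw(4), con)                        # 348 extension flag
  if (datatype == 2L) {
    writeBin(as.raw(as.integer(vals)), con)
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  close(con); on.exit(NULL)

  if (sidecar) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' @param path `.nii` path.
#' @return An [image_volume()] (masks come back as 0/1 `"fraction"` images).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop_invalid("not a NIfTI-1 file")
  invisible(readBin(con, "raw", n = 36))       # skip to dim
  dim8 <- ri(8, 2)
  dims <- dim8[2:4]
  invisible(rf(3)); invisible(ri(1, 2))        # intent_p, intent_code
  datatype <- ri(1, 2)
  invisible(ri(1, 2)); invisible(ri(1, 2))     # bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  invisible(readBin(con, "raw", n = 280 - 112))
  srow_x <- rf(4); srow_y <- rf(4); srow_z <- rf(4)
  origin <- c(srow_x[4], srow_y[4], srow_z[4])
  grid <- grid_spec(dims, pixdim[2:4], origin)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(dims)
  vals <- if (datatype == 2L) {
    as.numeric(readBin(con, "raw", n = n))
  } else if (datatype == 16L) {
    readBin(con, "numeric", n = n, size = 4, endian = "little")
  } else stop_invalid(sprintf("unsupported NIfTI datatype %d", datatype))

  meta_path <- paste0(path, ".json")
  unit <- "fraction"; prov <- ""
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    unit <- meta$value_unit %||% "fraction"
    prov <- meta$provenance %||% ""
  }
  image_volume(array(vals, dim = dims), grid, value_unit = unit,
               provenance = prov)
}
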