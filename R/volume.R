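# Spatial data model: CT volumes and congruent binary masks.
#
# Index convention: R arrays are 1-based; the centre of voxel (i, j, k) is at
# origin + (c(i, j, k) - 1) * spacing, in mm, in the frame named by the
# orientation tag. The internal working frame is always LPS.

HU_MIN <- -1024
HU_MAX <- 4000

#' CT volume in Hounsfield units
#'
#' A 3D voxel grid with physical spacing and origin, carrying calibrated CT
#' intensities (HU). This is the substrate for densitometry and for the
#' region-of-interest volumetry.
#'
#' @param data numeric 3D array of intensities in HU.
#' @param spacing length-3 positive numeric, voxel spacing in mm per axis.
#' @param origin length-3 numeric, physical position (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @param frame orientation tag; `"LPS"` (DICOM patient frame, the internal
#'   convention) or `"RAS"` (recorded provenance for NIfTI-sourced data that
#'   has been converted).
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' voxel_volume(vol)
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0), frame = "LPS") {
  if (length(dim(data)) != 3)
    stop("data must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive on all three axes", call. = FALSE)
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be three finite numbers", call. = FALSE)
  frame <- match.arg(frame, c("LPS", "RAS"))
  if (any(!is.finite(data)))
    stop("intensities must be finite", call. = FALSE)
  rng <- range(data)
  if (rng[1] < HU_MIN - 0.5 || rng[2] > HU_MAX + 0.5)
    warning(sprintf("intensities outside the plausible HU range [%d, %d]",
                    HU_MIN, HU_MAX))
  structure(list(data = data, spacing = spacing, origin = origin,
                 frame = frame),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm, frame %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$frame))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.2f, %.2f, %.2f) mm\n",
              min(x$data), max(x$data), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Binary segmentation mask congruent with a CT volume
#'
#' @param data logical 3D array (TRUE = foreground).
#' @inheritParams ct_volume
#' @return An object of class `ct_mask`.
#' @export
ct_mask <- function(data, spacing, origin = c(0, 0, 0), frame = "LPS") {
  if (length(dim(data)) != 3)
    stop("data must be a 3D array", call. = FALSE)
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask must not contain NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be strictly positive on all three axes", call. = FALSE)
  frame <- match.arg(frame, c("LPS", "RAS"))
  structure(list(data = data, spacing = spacing, origin = origin,
                 frame = frame),
            class = "ct_mask")
}

#' @export
print.ct_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_mask> %d x %d x %d voxels, %d foreground, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], sum(x$data),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Volume of one voxel in cubic millimetres
#' @param x a `ct_volume` or `ct_mask`.
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

# congruence: same grid geometry
check_congruent <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("mask shape does not match volume shape", call. = FALSE)
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9 ||
      max(abs(volume$origin - mask$origin)) > 1e-6)
    stop("mask grid (spacing/origin) does not match volume grid", call. = FALSE)
  invisible(TRUE)
}

#' Convert between voxel indices and physical coordinates
#'
#' `voxel_to_world()` maps 1-based voxel indices to mm coordinates of voxel
#' centres; `world_to_voxel()` is the inverse (continuous; round to get the
#' containing voxel).
#'
#' @param x a `ct_volume` or `ct_mask`.
#' @param index n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @param point n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return Matrix (or vector) of the converted coordinates.
#' @export
voxel_to_world <- function(x, index) {
  single <- is.null(dim(index))
  idx <- if (single) matrix(index, 1, 3) else as.matrix(index)
  out <- sweep(sweep(idx - 1, 2, x$spacing, "*"), 2, x$origin, "+")
  if (single) drop(out) else out
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(x, point) {
  single <- is.null(dim(point))
  p <- if (single) matrix(point, 1, 3) else as.matrix(point)
  out <- sweep(sweep(p, 2, x$origin, "-"), 2, x$spacing, "/") + 1
  if (single) drop(out) else out
}

# Physical coordinates (n x 3) of the centres of the given linear voxel
# indices (or all foreground voxels of a mask).
mask_foreground_coords <- function(mask) {
  idx <- which(mask$data)
  if (length(idx) == 0) return(matrix(numeric(0), 0, 3))
  voxel_to_world(mask, arrayInd(idx, dim(mask$data)))
}
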