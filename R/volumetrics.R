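# Condylar region of interest, voxel volumetry and HU densitometry.

#' Clip a mask to the condylar region of interest
#'
#' Retains the foreground voxels whose centres project onto the condylar axis
#' within `[0, depth)` mm below the apex — the standard region of interest
#' running from the highest edge of the condyle to a point 15 mm lower on the
#' condylar axis.
#'
#' @param mask a [ct_mask()].
#' @param axis length-3 direction pointing *down* the condylar axis (from the
#'   apex towards the ramus); normalised internally.
#' @param apex apex point, mm (must lie within or on the mask bounding box).
#' @param depth slab depth in mm (default 15). Use `Inf` for no clipping.
#' @return A [ct_mask()] whose foreground is a subset of the input's.
#' @export
clip_condylar_roi <- function(mask, axis, apex, depth = 15) {
  stopifnot(inherits(mask, "ct_mask"))
  if (!any(mask$data)) stop("mask is empty", call. = FALSE)
  if (is.na(depth)) stop("depth must be a number", call. = FALSE)
  if (is.infinite(depth) && depth > 0) return(mask)
  if (depth <= 0) stop("ROI empty: depth must be positive", call. = FALSE)
  u <- unit_vector(axis, "condylar axis")
  apex <- as.numeric(apex)
  lo <- voxel_to_world(mask, c(1, 1, 1)) - mask$spacing / 2
  hi <- voxel_to_world(mask, dim(mask$data)) + mask$spacing / 2
  if (any(apex < lo - 1e-9) || any(apex > hi + 1e-9))
    stop("apex outside the mask bounding box", call. = FALSE)
  idx <- which(mask$data)
  coords <- voxel_to_world(mask, arrayInd(idx, dim(mask$data)))
  t_ <- as.numeric(sweep(coords, 2, apex, "-") %*% u)
  keep <- t_ >= 0 & t_ < depth
  if (!any(keep))
    stop("ROI empty: check apex/axis", call. = FALSE)
  out <- array(FALSE, dim(mask$data))
  out[idx[keep]] <- TRUE
  ct_mask(out, spacing = mask$spacing, origin = mask$origin,
          frame = mask$frame)
}

#' Mask volume in cubic millimetres
#'
#' Foreground voxel count times per-voxel volume — the segmentation-software
#' readout of condylar volume.
#'
#' @param mask a [ct_mask()].
#' @return Volume in mm^3 (0 for an empty mask).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "ct_mask"))
  sum(mask$data) * voxel_volume(mask)
}

#' Mean bone density over a mask
#'
#' Arithmetic mean of the HU intensities over the mask foreground.
#'
#' @param volume a [ct_volume()].
#' @param mask a [ct_mask()] congruent with `volume` and nonempty.
#' @return Mean HU (scalar).
#' @export
mean_density <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "ct_mask"))
  check_congruent(volume, mask)
  if (!any(mask$data))
    stop("mask is empty: mean density undefined", call. = FALSE)
  mean(volume$data[mask$data])
}

#' Density record for one condyle and timepoint
#'
#' Convenience bundle of the volumetric/densitometric readouts for a region
#' of interest.
#'
#' @param volume a [ct_volume()].
#' @param mask the ROI [ct_mask()].
#' @param side,timepoint tags carried through to reports.
#' @return A list of class `density_record` with `mean_hu`, `n_voxels`,
#'   `volume_mm3`, `side`, `timepoint`.
#' @export
density_record <- function(volume, mask, side = NA_character_,
                           timepoint = NA_character_) {
  structure(list(mean_hu = mean_density(volume, mask),
                 n_voxels = sum(mask$data),
                 volume_mm3 = mask_volume(mask),
                 side = side, timepoint = timepoint),
            class = "density_record")
}

#' @export
print.density_record <- function(x, ...) {
  cat(sprintf("<density_record> %s %s: %.1f HU over %d voxels (%.0f mm^3)\n",
              x$side, x$timepoint, x$mean_hu, x$n_voxels, x$volume_mm3))
  invisible(x)
}

#' Percent change in mean density
#'
#' `100 * (post - pre) / pre` on mean HU; the clinical bone-density change.
#'
#' @param pre,post [density_record()] objects, or numbers (mean HU).
#' @return Percent change (full precision; round to 1 decimal for reports).
#' @examples
#' density_change(524.6, 406.5)  # -22.51...
#' @export
density_change <- function(pre, post) {
  pre_hu <- if (inherits(pre, "density_record")) pre$mean_hu else pre
  post_hu <- if (inherits(post, "density_record")) post$mean_hu else post
  if (!is.finite(pre_hu) || !is.finite(post_hu))
    stop("densities must be finite", call. = FALSE)
  if (pre_hu == 0) stop("percent change undefined: baseline density is zero",
                        call. = FALSE)
  100 * (post_hu - pre_hu) / pre_hu
}
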