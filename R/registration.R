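# Rigid surface registration (iterative closest point, point-to-surface).

# sensible grid cell for the accelerator: ~2x the median triangle size
default_cell_size <- function(mesh) {
  a <- face_areas(mesh$vertices, mesh$faces)
  max(2 * sqrt(stats::median(a)), 1e-3)
}

closest_points_on_mesh <- function(points, mesh, cell_size = NULL) {
  if (nrow(mesh$faces) == 0) stop("mesh has no faces", call. = FALSE)
  if (is.null(cell_size)) cell_size <- default_cell_size(mesh)
  cpp_closest_points(as.matrix(points), mesh$vertices, mesh$faces, cell_size)
}

#' Rigid registration of two surface meshes (ICP)
#'
#' Refines an initial rigid transform by iterative closest point: moving
#' vertices are matched to their closest points on the fixed surface
#' (point-to-surface, so the result does not depend on the fixed mesh's
#' vertex density) and the least-squares rigid motion is re-estimated until
#' the RMS correspondence distance changes by less than `tol` or `max_iter`
#' iterations are reached. No scaling is estimated: remodelling must not be
#' absorbed by a similarity transform.
#'
#' @param moving,fixed [surface_mesh()] objects.
#' @param init initial [rigid_transform()] mapping `moving` into the fixed
#'   frame (default identity).
#' @param moving_indices optional integer vector restricting the moving
#'   vertices used as registration support (e.g. the ramus stump below the
#'   condylar head, where remodelling is minimal).
#' @param max_iter,tol convergence controls (iterations; mm change in RMS).
#' @param n_sample maximum number of support vertices used per iteration
#'   (evenly subsampled, deterministic).
#' @param sanity_rms RMS (mm) above which the result is flagged as a likely
#'   non-overlap with a warning.
#' @return A [rigid_transform()] with attributes `rms` (final RMS, mm),
#'   `iterations`, and `suspect` (TRUE when `rms > sanity_rms`).
#' @export
register_rigid <- function(moving, fixed, init = rigid_transform(),
                           moving_indices = NULL, max_iter = 100,
                           tol = 1e-4, n_sample = 2000, sanity_rms = 10) {
  stopifnot(inherits(moving, "surface_mesh"), inherits(fixed, "surface_mesh"))
  if (nrow(moving$vertices) == 0 || nrow(fixed$vertices) == 0)
    stop("meshes must be nonempty", call. = FALSE)
  pts <- moving$vertices
  if (!is.null(moving_indices)) pts <- pts[moving_indices, , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 support vertices", call. = FALSE)
  if (nrow(pts) > n_sample) {
    keep <- round(seq(1, nrow(pts), length.out = n_sample))
    pts <- pts[keep, , drop = FALSE]
  }
  cell <- default_cell_size(fixed)
  transform <- init
  rms_prev <- Inf
  iterations <- 0
  for (it in seq_len(max_iter)) {
    iterations <- it
    cur <- transform_points(transform, pts)
    cp <- cpp_closest_points(cur, fixed$vertices, fixed$faces, cell)
    rms <- sqrt(mean(cp$distance^2))
    transform <- kabsch(pts, cp$point)
    if (abs(rms_prev - rms) < tol) break
    rms_prev <- rms
  }
  cur <- transform_points(transform, pts)
  cp <- cpp_closest_points(cur, fixed$vertices, fixed$faces, cell)
  rms <- sqrt(mean(cp$distance^2))
  suspect <- rms > sanity_rms
  if (suspect)
    warning(sprintf("registration RMS %.2f mm exceeds %.1f mm: surfaces may not overlap",
                    rms, sanity_rms))
  attr(transform, "rms") <- rms
  attr(transform, "iterations") <- iterations
  attr(transform, "suspect") <- suspect
  transform
}
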