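# End-to-end measurement of one condyle study and comparison of a pre/post
# pair: the six-parameter workflow.

#' Measure one condyle study
#'
#' Computes the per-timepoint parameters of one [condyle_study()]: ramus
#' height, intercondylar angle, condylar axis inclination, and — over the
#' condylar region of interest running `roi_depth` mm down the condylar axis
#' from the apex — volume and mean bone density.
#'
#' @param study a [condyle_study()].
#' @param roi_depth ROI depth along the condylar axis, mm (default 15).
#' @return A list of class `measurement_record` with `side`, `timepoint`,
#'   `height_mm`, `intercondylar_deg`, `axis_deg`, `volume_mm3`, `mean_hu`,
#'   `n_voxels`.
#' @export
measure_condyle <- function(study, roi_depth = 15) {
  stopifnot(inherits(study, "condyle_study"))
  lm <- study$landmarks
  frame <- condylar_frame(lm, study$side)
  apex <- get_landmark(lm, "condyle_apex")
  roi <- clip_condylar_roi(study$mask, axis = -frame$superior, apex = apex,
                           depth = roi_depth)
  structure(list(side = study$side, timepoint = study$timepoint,
                 height_mm = ramus_height(lm, study$side)$value,
                 intercondylar_deg = intercondylar_angle(lm)$value,
                 axis_deg = condylar_axis_inclination(lm)$value,
                 volume_mm3 = mask_volume(roi),
                 mean_hu = mean_density(study$volume, roi),
                 n_voxels = sum(roi$data)),
            class = "measurement_record")
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf(paste0("<measurement_record> %s %s: height %.1f mm, ",
                     "intercondylar %.1f deg, axis %.1f deg, ",
                     "%.0f mm^3, %.1f HU\n"),
              x$side, x$timepoint, x$height_mm, x$intercondylar_deg,
              x$axis_deg, x$volume_mm3, x$mean_hu))
  invisible(x)
}

# vertex indices of the condylar head (top `cap_mm` of the mesh along the
# superior axis) and of the registration support (everything below)
split_head_support <- function(mesh, superior, cap_mm = 20) {
  h <- as.vector(mesh$vertices %*% superior)
  top <- max(h)
  head_idx <- which(h > top - cap_mm)
  support_idx <- which(h <= top - cap_mm)
  list(head = head_idx, support = support_idx)
}

#' Compare a pre/post pair of condyle studies
#'
#' Runs the full remodelling pipeline on one condyle: measures both
#' timepoints ([measure_condyle()]), rigidly registers the follow-up mesh to
#' the baseline mesh (ICP initialised by aligning the landmark-derived
#' condylar frames), computes the signed apposition/resorption distance map
#' over the condylar head, partitions the head into the five anatomical
#' surfaces, and reports all six deltas.
#'
#' Registration support: with `registration = "support"` (default) only
#' vertices below the superior `head_cap_mm` cap — the ramus stump, where
#' remodelling is minimal — drive the ICP, so genuine head remodelling is not
#' absorbed into the rigid alignment. `"full"` uses the whole mesh.
#'
#' @param pre,post [condyle_study()] objects for T0 and T1 of the same side.
#' @param roi_depth ROI depth for volume/density, mm.
#' @param registration `"support"` or `"full"`.
#' @param head_cap_mm boundary of the registration support below the mesh's
#'   topmost point, mm.
#' @param measure_cap_mm extent of the measured head region below the topmost
#'   point, mm; kept smaller than `head_cap_mm` so the measured region stays
#'   clear of the head/ramus junction.
#' @param compute_surfaces set FALSE to skip registration and the distance
#'   map (landmark and voxel deltas only).
#' @return A list of class `condyle_comparison`: `pre`, `post`
#'   (measurement records), `deltas` (list: `height_mm`, `height_pct`,
#'   `intercondylar_deg`, `axis_deg`, `volume_mm3`, `volume_pct`,
#'   `density_hu`, `density_pct`, `resorption` flag, and — when surfaces are
#'   computed — `surfaces`, the [per_surface_means()] data.frame),
#'   `transform` (the registration result) and `distmap`.
#' @export
compare_condyle_studies <- function(pre, post, roi_depth = 15,
                                    registration = c("support", "full"),
                                    head_cap_mm = 20, measure_cap_mm = 12,
                                    compute_surfaces = TRUE) {
  stopifnot(inherits(pre, "condyle_study"), inherits(post, "condyle_study"))
  if (!identical(pre$side, post$side))
    stop("pre and post studies must be the same side", call. = FALSE)
  registration <- match.arg(registration)
  m0 <- measure_condyle(pre, roi_depth)
  m1 <- measure_condyle(post, roi_depth)
  deltas <- list(
    height_mm = m1$height_mm - m0$height_mm,
    height_pct = measurement_delta(m0$height_mm, m1$height_mm,
                                   as_percent = TRUE),
    intercondylar_deg = m1$intercondylar_deg - m0$intercondylar_deg,
    axis_deg = m1$axis_deg - m0$axis_deg,
    volume_mm3 = m1$volume_mm3 - m0$volume_mm3,
    volume_pct = measurement_delta(m0$volume_mm3, m1$volume_mm3,
                                   as_percent = TRUE),
    density_hu = m1$mean_hu - m0$mean_hu,
    density_pct = density_change(m0$mean_hu, m1$mean_hu))
  deltas$resorption <- classify_resorption(deltas$height_pct)
  transform <- NULL
  distmap <- NULL
  if (compute_surfaces) {
    frame0 <- condylar_frame(pre$landmarks, pre$side)
    frame1 <- condylar_frame(post$landmarks, post$side)
    B0 <- cbind(frame0$anterior, frame0$medial, frame0$superior)
    B1 <- cbind(frame1$anterior, frame1$medial, frame1$superior)
    R0 <- B0 %*% t(B1)
    if (det(R0) < 0) R0 <- B0 %*% diag(c(1, -1, 1)) %*% t(B1)
    init <- rigid_transform(R0, frame0$origin - as.numeric(R0 %*% frame1$origin))
    sel1 <- split_head_support(post$mesh, frame1$superior, head_cap_mm)
    support <- if (registration == "support" && length(sel1$support) >= 100)
      sel1$support else NULL
    transform <- register_rigid(post$mesh, pre$mesh, init = init,
                                moving_indices = support,
                                tol = 1e-6, max_iter = 300)
    post_in_pre <- transform_mesh(post$mesh, transform)
    sel0 <- split_head_support(pre$mesh, frame0$superior, measure_cap_mm)
    distmap <- signed_distances(pre$mesh, post_in_pre,
                                vertex_indices = sel0$head)
    labels <- partition_condylar_surface(pre$mesh, frame0)
    deltas$surfaces <- per_surface_means(distmap, labels)
  }
  structure(list(pre = m0, post = m1, deltas = deltas, transform = transform,
                 distmap = distmap),
            class = "condyle_comparison")
}

#' @export
print.condyle_comparison <- function(x, ...) {
  d <- x$deltas
  cat(sprintf("<condyle_comparison> %s condyle, T0 -> T1\n", x$pre$side))
  cat(sprintf("  height %+0.2f mm (%+0.2f%%)%s\n", d$height_mm, d$height_pct,
              if (d$resorption) " [resorption >6%]" else ""))
  cat(sprintf("  intercondylar %+0.2f deg, axis %+0.2f deg\n",
              d$intercondylar_deg, d$axis_deg))
  cat(sprintf("  volume %+0.0f mm^3 (%+0.2f%%), density %+0.1f HU (%+0.1f%%)\n",
              d$volume_mm3, d$volume_pct, d$density_hu, d$density_pct))
  if (!is.null(d$surfaces)) {
    cat("  surfaces (mean mm):",
        paste(sprintf("%s %+0.2f", d$surfaces$surface, d$surfaces$mean_mm),
              collapse = ", "), "\n")
  }
  invisible(x)
}
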