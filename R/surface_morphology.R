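# Signed apposition/resorption distance maps, anatomical surface
# parcellation, per-region summaries and colour-map export.

#' Signed surface distances (apposition/resorption map)
#'
#' For each vertex of the reference mesh, the distance to the closest point
#' on the target surface, signed positive when the target lies outward along
#' the reference outward normal (bone apposition, rendered red) and negative
#' when it lies inward (bone resorption, rendered blue). The target must
#' already be registered into the reference frame (see [register_rigid()]).
#'
#' @param reference the baseline [surface_mesh()] (distances are attached to
#'   its vertices).
#' @param target the follow-up [surface_mesh()], in the reference frame.
#' @param vertex_indices optional integer vector restricting the computation
#'   to a subset of reference vertices.
#' @return A list of class `distance_map`: `distance` (signed mm, one per
#'   requested vertex), `vertex` (indices into the reference mesh),
#'   `reference` tag.
#' @export
signed_distances <- function(reference, target, vertex_indices = NULL) {
  stopifnot(inherits(reference, "surface_mesh"),
            inherits(target, "surface_mesh"))
  nrm <- vertex_normals(reference)
  bad <- rowSums(nrm^2) < 0.5
  if (any(bad[if (is.null(vertex_indices)) TRUE else vertex_indices]))
    stop("mesh has vertices without consistent outward normals; re-orient the mesh",
         call. = FALSE)
  idx <- if (is.null(vertex_indices)) seq_len(nrow(reference$vertices))
         else as.integer(vertex_indices)
  pts <- reference$vertices[idx, , drop = FALSE]
  cp <- closest_points_on_mesh(pts, target)
  disp <- cp$point - pts
  s <- sign(rowSums(disp * nrm[idx, , drop = FALSE]))
  s[s == 0] <- 1
  structure(list(distance = s * cp$distance, vertex = idx,
                 reference = "T0"),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %d vertices, mean %+.3f mm, range [%+.3f, %+.3f] mm\n",
              length(x$distance), mean(x$distance), min(x$distance),
              max(x$distance)))
  invisible(x)
}

SURFACE_LABELS <- c("anterior", "posterior", "medial", "lateral", "superior")

#' Partition a condylar surface into five anatomical regions
#'
#' Labels every vertex as `superior`, `anterior`, `posterior`, `medial` or
#' `lateral` relative to a condylar local frame: a vertex is `superior` when
#' its direction from the frame origin makes less than `cone_deg` (default
#' 45) degrees with the superior axis; otherwise it is labelled by the
#' azimuthal quadrant (90 degrees wide, centred on the frame axes) of its
#' origin-relative direction in the anterior-medial plane.
#'
#' @param mesh a [surface_mesh()].
#' @param frame a condylar frame as returned by [condylar_frame()]: a list
#'   with `origin`, `superior`, `anterior`, `medial` (orthonormal).
#' @param cone_deg half-angle of the superior cone, degrees.
#' @return A factor of length `nrow(mesh$vertices)` with the five levels
#'   (a total partition: every vertex gets exactly one label).
#' @export
partition_condylar_surface <- function(mesh, frame, cone_deg = 45) {
  stopifnot(inherits(mesh, "surface_mesh"))
  check_frame(frame)
  if (nrow(mesh$vertices) == 0) stop("mesh is empty", call. = FALSE)
  rel <- sweep(mesh$vertices, 2, frame$origin, "-")
  len <- sqrt(rowSums(rel^2))
  if (any(len < 1e-12))
    len[len < 1e-12] <- 1  # vertex at the origin: falls through to azimuth 0
  up <- rel %*% frame$superior / len
  a <- rel %*% frame$anterior
  m <- rel %*% frame$medial
  az <- atan2(m, a) * 180 / pi   # 0 = anterior, +90 = medial
  lab <- character(nrow(rel))
  lab[az > -45 & az <= 45] <- "anterior"
  lab[az > 45 & az <= 135] <- "medial"
  lab[az > 135 | az <= -135] <- "posterior"
  lab[az > -135 & az <= -45] <- "lateral"
  lab[up >= cos(cone_deg * pi / 180)] <- "superior"
  factor(lab, levels = SURFACE_LABELS)
}

check_frame <- function(frame) {
  need <- c("origin", "superior", "anterior", "medial")
  if (!is.list(frame) || !all(need %in% names(frame)))
    stop("frame must be a list with origin, superior, anterior, medial",
         call. = FALSE)
  B <- rbind(frame$superior, frame$anterior, frame$medial)
  if (any(!is.finite(B)) || max(abs(B %*% t(B) - diag(3))) > 1e-6)
    stop("degenerate frame: axes must be orthonormal", call. = FALSE)
  invisible(TRUE)
}

#' Per-region mean signed distances
#'
#' Arithmetic mean (and SD, count) of the signed distances per anatomical
#' surface label. A label with no vertices is reported as `NA`.
#'
#' @param distmap a [signed_distances()] result.
#' @param labels the label factor from [partition_condylar_surface()] for the
#'   same reference mesh.
#' @return A data.frame with columns `surface`, `mean_mm`, `sd_mm`,
#'   `n_vertices` (one row per label, all five always present).
#' @export
per_surface_means <- function(distmap, labels) {
  stopifnot(inherits(distmap, "distance_map"))
  lab <- labels[distmap$vertex]
  mean_mm <- tapply(distmap$distance, lab, mean)
  sd_mm <- tapply(distmap$distance, lab, stats::sd)
  n <- tapply(distmap$distance, lab, length)
  data.frame(surface = SURFACE_LABELS,
             mean_mm = as.numeric(mean_mm[SURFACE_LABELS]),
             sd_mm = as.numeric(sd_mm[SURFACE_LABELS]),
             n_vertices = as.integer(ifelse(is.na(n[SURFACE_LABELS]), 0,
                                            n[SURFACE_LABELS])),
             row.names = NULL)
}

#' Export a red/blue remodelling colour-map as PLY
#'
#' Writes the reference mesh with the signed-distance scalar channel and an
#' 8-bit diverging colour channel: blue for resorption (negative), red for
#' apposition (positive), white at zero, clamped symmetrically at
#' `|d| = dmax`.
#'
#' @param mesh the reference [surface_mesh()].
#' @param distmap a [signed_distances()] result covering every mesh vertex.
#' @param path output `.ply` file.
#' @param dmax symmetric clamp (mm) for colour saturation.
#' @return `path`, invisibly.
#' @export
export_colormap <- function(mesh, distmap, path, dmax = 1.0) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(distmap, "distance_map"))
  d <- rep(NA_real_, nrow(mesh$vertices))
  d[distmap$vertex] <- distmap$distance
  if (anyNA(d))
    stop("distance map does not cover every mesh vertex", call. = FALSE)
  x <- pmax(-1, pmin(1, d / dmax))
  # diverging blue-white-red
  red <- ifelse(x >= 0, 255, round(255 * (1 + x)))
  blue <- ifelse(x <= 0, 255, round(255 * (1 - x)))
  green <- round(255 * (1 - abs(x)))
  mesh$scalars <- d
  write_ply(mesh, path, colors = cbind(red, green, blue))
  invisible(path)
}
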