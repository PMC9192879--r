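# Synthetic condyle phantom: a capsule-like ramus topped by an ellipsoidal
# condylar head, voxelised in HU (cortical shell + noisy trabecular core),
# with analytic landmarks and exact ground truth for all six remodelling
# parameters. Deliberately schematic: ground-truth tractability matters more
# than anatomical realism for validating the measurement operators.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

smoothstep <- function(x, lo, hi) {
  t <- pmin(1, pmax(0, (x - lo) / (hi - lo)))
  t * t * (3 - 2 * t)
}

#' Phantom geometry and tissue specification
#'
#' Describes the synthetic condyle: a capsule ramus (cylinder with a
#' hemispherical lower cap) whose axis is tilted in the coronal plane, topped
#' by an ellipsoidal head. Bone is a cortical shell over a noisy trabecular
#' core; background is air.
#'
#' @param ramus_length_mm apex-to-gonion distance (this *is* the ground-truth
#'   ramus height), default 62.
#' @param ramus_radius_mm capsule radius, default 6.
#' @param head_semiaxes_mm length-3: medio-lateral, antero-posterior and
#'   axial semi-axes of the head ellipsoid, default c(10, 8, 8).
#' @param ramus_tilt_deg coronal tilt of the ramus axis from vertical,
#'   default 15.
#' @param shell_thickness_mm cortical shell thickness, default 1.5.
#' @param cortical_hu shell intensity, default 1400.
#' @param trabecular_mean_hu,trabecular_sd_hu core intensity distribution,
#'   defaults 550 and 50.
#' @param spacing_mm isotropic voxel spacing; keep at or below 0.5 for
#'   parameter-recovery work, default 0.5.
#' @param side `"left"` (default) or `"right"`.
#' @param seed RNG seed for the trabecular noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(ramus_length_mm = 62, ramus_radius_mm = 6,
                         head_semiaxes_mm = c(10, 8, 8),
                         ramus_tilt_deg = 15, shell_thickness_mm = 1.5,
                         cortical_hu = 1400, trabecular_mean_hu = 550,
                         trabecular_sd_hu = 50, spacing_mm = 0.5,
                         side = "left", seed = 1) {
  side <- match.arg(side, c("left", "right"))
  spec <- list(ramus_length_mm = ramus_length_mm,
               ramus_radius_mm = ramus_radius_mm,
               head_semiaxes_mm = as.numeric(head_semiaxes_mm),
               ramus_tilt_deg = ramus_tilt_deg,
               shell_thickness_mm = shell_thickness_mm,
               cortical_hu = cortical_hu,
               trabecular_mean_hu = trabecular_mean_hu,
               trabecular_sd_hu = trabecular_sd_hu,
               spacing_mm = spacing_mm, side = side, seed = as.integer(seed))
  lens <- c(ramus_length_mm, ramus_radius_mm, head_semiaxes_mm,
            shell_thickness_mm, spacing_mm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths must be positive", call. = FALSE)
  if (cortical_hu <= trabecular_mean_hu)
    stop("cortical HU must exceed the trabecular mean", call. = FALSE)
  if (spacing_mm > shell_thickness_mm)
    stop("spacing too coarse to resolve the cortical shell", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

# analytic geometry shared by generation and remodelling
phantom_geometry <- function(spec) {
  tilt <- spec$ramus_tilt_deg * pi / 180
  mirror <- if (spec$side == "left") 1 else -1
  u <- c(mirror * sin(tilt), 0, cos(tilt))          # ramus axis, up
  a <- spec$head_semiaxes_mm
  gonion <- c(mirror * 30, 0, 5)
  apex <- gonion + spec$ramus_length_mm * u
  O <- apex - a[3] * u                              # head centre
  B <- gonion + spec$ramus_radius_mm * u            # bottom cap centre
  e2 <- c(0, 1, 0)
  e1 <- cross3(e2, u)                               # medio-lateral, unit
  anterior <- c(0, -1, 0)
  medial <- cross3(u, anterior)            # in the coronal plane, unit
  if (medial[1] * (-mirror) < 0) medial <- -medial
  frame <- list(origin = O, superior = u, anterior = anterior,
                medial = medial)
  list(u = u, e1 = e1, e2 = e2, gonion = gonion, apex = apex, O = O, B = B,
       frame = frame, mirror = mirror)
}

phantom_landmarks <- function(spec, g) {
  a <- spec$head_semiaxes_mm
  center_this <- g$O
  center_other <- g$O * c(-1, 1, 1)                 # mirrored contralateral
  vertex <- c(0, g$O[2] - 25, g$O[3] - 20)
  pts <- list(
    condyle_apex = g$apex,
    gonion_lowest = g$gonion,
    transverse_diameter_1 = g$O - a[1] * g$e1,
    transverse_diameter_2 = g$O + a[1] * g$e1,
    ramus_axis_1 = g$B,
    ramus_axis_2 = g$O,
    foramen_magnum_anterior = vertex)
  if (spec$side == "left") {
    pts$condyle_center_left <- center_this
    pts$condyle_center_right <- center_other
  } else {
    pts$condyle_center_right <- center_this
    pts$condyle_center_left <- center_other
  }
  landmark_set(pts)
}

# squared normalised ellipsoid coordinate and capsule surface distance for
# a coordinate matrix (n x 3)
phantom_inside <- function(coords, g, semiaxes, radius) {
  dO <- sweep(coords, 2, g$O, "-")
  rho2 <- (dO %*% g$e1 / semiaxes[1])^2 + (dO %*% g$e2 / semiaxes[2])^2 +
    (dO %*% g$u / semiaxes[3])^2
  # distance to segment [B, O]
  seg <- g$O - g$B
  seg_len2 <- sum(seg^2)
  dB <- sweep(coords, 2, g$B, "-")
  t_ <- pmin(1, pmax(0, (dB %*% seg) / seg_len2))
  closest <- cbind(g$B[1] + t_ * seg[1], g$B[2] + t_ * seg[2],
                   g$B[3] + t_ * seg[3])
  d2 <- rowSums((coords - closest)^2)
  as.vector(rho2 <= 1 | d2 <= radius^2)
}

#' Generate a synthetic condyle study (baseline)
#'
#' Voxelises the phantom in HU, derives the binary mask from the bone
#' support, extracts the voxel-boundary surface mesh and emits the analytic
#' landmark set — all with exact ground truth recorded.
#'
#' @param spec a [phantom_spec()].
#' @param with_mesh extract the surface mesh (set FALSE to skip the most
#'   expensive step when only voxel measurements are needed).
#' @param smooth_iterations Taubin smoothing passes applied to the extracted
#'   voxel-boundary mesh (see [mesh_smooth()]); 0 keeps the raw staircase
#'   surface.
#' @return A list of class `phantom`: `study` (a [condyle_study()] at T0),
#'   `truth` (ground-truth values of the six parameters), `core_mask`
#'   (trabecular core, shell excluded), `frame` (the condylar local frame)
#'   and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(spacing_mm = 1.5,
#'                                     shell_thickness_mm = 2))
#' ph$truth$height_mm
#' @export
generate_phantom <- function(spec, with_mesh = TRUE,
                             smooth_iterations = 20) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  a <- spec$head_semiaxes_mm
  r <- spec$ramus_radius_mm
  sp <- spec$spacing_mm
  pad <- 3
  ext <- rbind(g$O - a[1] - pad, g$O + a[1] + pad,
               g$gonion - r - pad, g$gonion + r + pad,
               g$B - r - pad, g$B + r + pad,
               g$apex - pad, g$apex + pad)
  lo <- apply(ext, 2, min); hi <- apply(ext, 2, max)
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / sp)) + 1L)
  origin <- lo
  # voxel-centre coordinates, axis by axis (memory-friendly outer products)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * sp
  ys <- origin[2] + (seq_len(dims[2]) - 1) * sp
  zs <- origin[3] + (seq_len(dims[3]) - 1) * sp
  coords <- cbind(rep(xs, times = dims[2] * dims[3]),
                  rep(rep(ys, each = dims[1]), times = dims[3]),
                  rep(zs, each = dims[1] * dims[2]))
  inside <- phantom_inside(coords, g, a, r)
  t_ <- spec$shell_thickness_mm
  core <- phantom_inside(coords, g, pmax(a - t_, 1e-6), max(r - t_, 1e-6))
  mask_arr <- array(inside, dims)
  core_arr <- array(core & inside, dims)
  hu <- array(-1000, dims)
  hu[mask_arr] <- spec$cortical_hu
  n_core <- sum(core_arr)
  hu[core_arr] <- with_seed(spec$seed,
                            rnorm(n_core, spec$trabecular_mean_hu,
                                  spec$trabecular_sd_hu))
  hu[] <- pmin(pmax(hu, HU_MIN), HU_MAX)
  volume <- ct_volume(hu, spacing = rep(sp, 3), origin = origin)
  mask <- ct_mask(mask_arr, spacing = rep(sp, 3), origin = origin)
  core_mask <- ct_mask(core_arr, spacing = rep(sp, 3), origin = origin)
  landmarks <- phantom_landmarks(spec, g)
  mesh <- if (with_mesh) mesh_smooth(mesh_from_mask(mask),
                                     iterations = smooth_iterations)
          else surface_mesh(matrix(numeric(0), 0, 3),
                            matrix(integer(0), 0, 3))
  study <- condyle_study(spec$side, "T0", volume, mask, mesh, landmarks)
  truth <- list(
    height_mm = spec$ramus_length_mm,
    intercondylar_deg = intercondylar_angle(landmarks)$value,
    axis_deg = condylar_axis_inclination(landmarks)$value,
    volume_mm3 = mask_volume(mask),
    mean_hu = mean_density(volume, mask),
    trabecular_mean_hu = if (n_core > 0) mean(volume$data[core_arr])
                         else NA_real_,
    surface_offsets_mm = stats::setNames(rep(0, 5), SURFACE_LABELS))
  structure(list(study = study, truth = truth, core_mask = core_mask,
                 frame = g$frame, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s condyle %s, height %.1f mm, %.0f mm^3, mean %.1f HU\n",
              x$study$side, x$study$timepoint, x$truth$height_mm,
              x$truth$volume_mm3, x$truth$mean_hu))
  invisible(x)
}

#' Prescribed remodelling between the phantom's two timepoints
#'
#' @param height_delta_mm change in ramus height (apex displaced along the
#'   apex-gonion line).
#' @param axis_rotation_deg coronal-plane rotation applied to the transverse
#'   diameter landmarks (realised condylar-axis change).
#' @param intercondylar_delta_deg change of the intercondylar angle (the
#'   contralateral condylar centre is rotated about the foramen vertex).
#' @param surface_offsets_mm named length-5 numeric (anterior, posterior,
#'   medial, lateral, superior): outward-normal displacement of the condylar
#'   head surface per region, blended over a 10 degree band at region borders
#'   and tapered to zero at the head/ramus junction. Must be within +-2 mm.
#' @param density_scale multiplicative HU factor inside the mask, in (0, 2].
#' @param hu_noise_sd additive HU noise SD applied with the scaling.
#' @param seed RNG seed for the noise.
#' @return A list of class `remodel_spec`.
#' @export
remodel_spec <- function(height_delta_mm = 0, axis_rotation_deg = 0,
                         intercondylar_delta_deg = 0,
                         surface_offsets_mm = c(anterior = 0, posterior = 0,
                                                medial = 0, lateral = 0,
                                                superior = 0),
                         density_scale = 1, hu_noise_sd = 0, seed = 2) {
  offs <- rep(0, 5)
  names(offs) <- SURFACE_LABELS
  if (!is.null(names(surface_offsets_mm))) {
    unknown <- setdiff(names(surface_offsets_mm), SURFACE_LABELS)
    if (length(unknown))
      stop("unknown surface label: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    offs[names(surface_offsets_mm)] <- surface_offsets_mm
  } else {
    stopifnot(length(surface_offsets_mm) == 5)
    offs[] <- surface_offsets_mm
  }
  if (any(abs(offs) > 2))
    stop("surface offsets must be within +-2 mm", call. = FALSE)
  if (!is.finite(density_scale) || density_scale <= 0 || density_scale > 2)
    stop("density scale must be in (0, 2]", call. = FALSE)
  structure(list(height_delta_mm = height_delta_mm,
                 axis_rotation_deg = axis_rotation_deg,
                 intercondylar_delta_deg = intercondylar_delta_deg,
                 surface_offsets_mm = offs, density_scale = density_scale,
                 hu_noise_sd = hu_noise_sd, seed = as.integer(seed)),
            class = "remodel_spec")
}

# region weight field for the offset blend: rows = vertices, one column per
# surface label; rows sum to 1
region_weights <- function(vertices, frame, blend_deg = 10, cone_deg = 45,
                           taper_from = NULL, taper_mm = 2) {
  rel <- sweep(vertices, 2, frame$origin, "-")
  len <- pmax(sqrt(rowSums(rel^2)), 1e-12)
  polar <- acos(pmin(1, pmax(-1, rel %*% frame$superior / len))) * 180 / pi
  az <- atan2(rel %*% frame$medial, rel %*% frame$anterior) * 180 / pi
  w_sup <- smoothstep(-polar, -(cone_deg + blend_deg / 2),
                      -(cone_deg - blend_deg / 2))
  centers <- c(anterior = 0, medial = 90, posterior = 180, lateral = -90)
  w_az <- sapply(centers, function(c0) {
    d <- abs((az - c0 + 180) %% 360 - 180)
    smoothstep(-d, -(45 + blend_deg / 2), -(45 - blend_deg / 2))
  })
  w_az <- w_az / pmax(rowSums(w_az), 1e-12)
  w <- cbind(w_az * as.vector(1 - w_sup), superior = as.vector(w_sup))
  w <- w[, SURFACE_LABELS, drop = FALSE]
  if (!is.null(taper_from)) {
    h <- as.vector(rel %*% frame$superior)
    w <- w * smoothstep(h, taper_from, taper_from + taper_mm)
  }
  w
}

#' Apply prescribed remodelling to a baseline phantom
#'
#' Produces the follow-up (T1) study: the apex landmark is displaced to
#' realise the height change, the transverse-diameter landmarks are rotated
#' in the coronal plane (condylar axis change), the contralateral condylar
#' centre is rotated about the foramen vertex (intercondylar change), the
#' head surface is displaced along outward vertex normals by the per-region
#' offsets, and the HU volume inside the mask is scaled and noised. Ground
#' truth is updated to the exactly realised deltas.
#'
#' @param phantom a [generate_phantom()] result (timepoint T0).
#' @param remodel a [remodel_spec()].
#' @return A list of class `phantom_pair`: `pre` and `post`
#'   ([condyle_study()] objects), `truth` (realised deltas: `height_delta_mm`,
#'   `axis_delta_deg`, `intercondylar_delta_deg`, `volume_delta_pct`,
#'   `density_delta_pct`, `surface_offsets_mm`, plus
#'   `realized_surface_means_mm` over the head region), `frame`, `spec`,
#'   `remodel`.
#' @export
apply_remodeling <- function(phantom, remodel) {
  stopifnot(inherits(phantom, "phantom"), inherits(remodel, "remodel_spec"))
  spec <- phantom$spec
  g <- phantom_geometry(spec)
  study0 <- phantom$study
  lm0 <- study0$landmarks
  pts <- lm0$points
  # height: displace the apex along the apex-gonion line
  up <- unit_vector(pts$condyle_apex - pts$gonion_lowest, "ramus line")
  pts$condyle_apex <- pts$condyle_apex + remodel$height_delta_mm * up
  # condylar axis: rotate the transverse endpoints in the coronal plane
  Rc <- rotation_about_axis(c(0, 1, 0), remodel$axis_rotation_deg)
  mid <- (pts$transverse_diameter_1 + pts$transverse_diameter_2) / 2
  pts$transverse_diameter_1 <- mid +
    as.numeric(Rc %*% (pts$transverse_diameter_1 - mid))
  pts$transverse_diameter_2 <- mid +
    as.numeric(Rc %*% (pts$transverse_diameter_2 - mid))
  # intercondylar: rotate the contralateral centre about the foramen vertex
  other <- if (spec$side == "left") "condyle_center_right"
           else "condyle_center_left"
  this <- if (spec$side == "left") "condyle_center_left"
          else "condyle_center_right"
  v <- pts$foramen_magnum_anterior
  va <- pts[[this]] - v
  vb <- pts[[other]] - v
  n_axis <- cross3(va, vb)
  if (vec_norm(n_axis) > 1e-9 && remodel$intercondylar_delta_deg != 0) {
    Rn <- rotation_about_axis(n_axis, remodel$intercondylar_delta_deg)
    pts[[other]] <- v + as.numeric(Rn %*% vb)
  }
  lm1 <- landmark_set(pts)
  # surface: per-region outward offsets on the head, blended and tapered
  mesh0 <- study0$mesh
  if (nrow(mesh0$vertices) > 0) {
    w <- region_weights(mesh0$vertices, phantom$frame,
                        taper_from = -spec$head_semiaxes_mm[3])
    off <- as.vector(w %*% remodel$surface_offsets_mm[SURFACE_LABELS])
    nrm <- vertex_normals(mesh0)
    verts1 <- mesh0$vertices + off * nrm
    mesh1 <- surface_mesh(verts1, mesh0$faces, clean = FALSE)
    if (any(abs(off) > 0) ) {
      # cheap self-intersection guard: offsets must not exceed local scale
      if (max(abs(off)) > min(spec$head_semiaxes_mm) / 2)
        stop("surface offsets cause self-intersection", call. = FALSE)
    }
    # realised per-region mean of the applied offset over the fully-weighted
    # head region (taper and blend excluded)
    labels <- partition_condylar_surface(mesh0, phantom$frame)
    h <- as.vector(sweep(mesh0$vertices, 2, phantom$frame$origin, "-") %*%
                     phantom$frame$superior)
    in_head <- h > -spec$head_semiaxes_mm[3] + 2
    realized <- tapply(off[in_head], labels[in_head], mean)
    realized <- stats::setNames(as.numeric(realized[SURFACE_LABELS]),
                                SURFACE_LABELS)
  } else {
    mesh1 <- mesh0
    realized <- stats::setNames(rep(NA_real_, 5), SURFACE_LABELS)
  }
  # density: scale + noise inside the mask
  vol1 <- study0$volume
  sel <- study0$mask$data
  vals <- vol1$data[sel] * remodel$density_scale
  if (remodel$hu_noise_sd > 0)
    vals <- vals + with_seed(remodel$seed,
                             rnorm(length(vals), 0, remodel$hu_noise_sd))
  vol1$data[sel] <- pmin(pmax(vals, HU_MIN), HU_MAX)
  study1 <- condyle_study(spec$side, "T1", vol1, study0$mask, mesh1, lm1)
  truth <- list(
    height_delta_mm = ramus_height(lm1)$value - ramus_height(lm0)$value,
    axis_delta_deg = condylar_axis_inclination(lm1)$value -
      condylar_axis_inclination(lm0)$value,
    intercondylar_delta_deg = intercondylar_angle(lm1)$value -
      intercondylar_angle(lm0)$value,
    volume_delta_pct = 0,
    density_delta_pct = density_change(mean_density(study0$volume, study0$mask),
                                       mean_density(vol1, study0$mask)),
    surface_offsets_mm = remodel$surface_offsets_mm,
    realized_surface_means_mm = realized,
    t0 = phantom$truth)
  structure(list(pre = study0, post = study1, truth = truth,
                 frame = phantom$frame, spec = spec, remodel = remodel),
            class = "phantom_pair")
}

#' Generate a synthetic paired cohort
#'
#' Builds `n_patients` seeded phantom pairs (two sides per patient) with
#' per-patient remodelling parameters drawn from stated distributions, and
#' (optionally) measures every pair with the full pipeline, returning the
#' long measurement table consumed by [build_cohort_report()] plus the exact
#' truth table. The default distributions emulate a bimaxillary-surgery
#' cohort: height change N(-0.7, 0.8) mm; condylar axis change N(+6.9, 8.9)
#' right / N(+1.05, 6.71) left; intercondylar change N(-10.8, 8.22) per
#' patient; density change percent N(-33.74, 4.45); per-region surface
#' offsets N((0.09, -0.03, 0.11, 0.01, 0.02), 0.3) truncated to +-1.5 mm.
#' Metadata scheme: every third patient is female; patients after the first
#' five-sixths are dysmorphism class II, the rest class III.
#'
#' @param n_patients number of patients (>= 2), default 12.
#' @param base_spec the [phantom_spec()] shared by all patients (per-pair
#'   seeds are derived from `seed`).
#' @param remodel_sampler function(patient, side) returning a
#'   [remodel_spec()]; the default draws from the distributions above.
#' @param seed master seed for the cohort.
#' @param measure run [measure_condyle()] on every study (default TRUE).
#' @param compute_surfaces also run the registration + signed-distance
#'   pipeline per pair (the expensive step), default FALSE.
#' @return A list of class `phantom_cohort`: `measurements` (long
#'   data.frame: patient, side, variable, delta, ...), `truth` (data.frame of
#'   prescribed/realised deltas), `metadata` (sex, dysmorphism), `pairs`
#'   (the phantom_pair objects, kept only when `keep_pairs = TRUE`).
#' @param keep_pairs retain the full phantom pairs (memory-heavy).
#' @export
generate_cohort <- function(n_patients = 12, base_spec = phantom_spec(),
                            remodel_sampler = NULL, seed = 1,
                            measure = TRUE, compute_surfaces = FALSE,
                            keep_pairs = FALSE) {
  if (n_patients < 2) stop("need at least 2 patients", call. = FALSE)
  seed <- as.integer(seed)
  sides <- c("right", "left")
  if (is.null(remodel_sampler)) {
    remodel_sampler <- function(patient, side) {
      # truncation keeps pathological tail draws inside the phantom's
      # geometric validity range; it is >3 SD out for every parameter
      height <- max(min(rnorm(1, -0.7, 0.8), 2.5), -3.5)
      axis <- if (side == "right") rnorm(1, 6.9, 8.9) else rnorm(1, 1.05, 6.71)
      axis <- max(min(axis, 40), -40)
      inter <- max(min(rnorm(1, -10.8, 8.22), 30), -45)
      dens_pct <- max(min(rnorm(1, -33.74, 4.45), 80), -80)
      offs <- pmin(pmax(rnorm(5, c(0.09, -0.03, 0.11, 0.01, 0.02), 0.3),
                        -1.5), 1.5)
      names(offs) <- SURFACE_LABELS
      remodel_spec(height_delta_mm = height, axis_rotation_deg = axis,
                   intercondylar_delta_deg = if (side == "left") inter else 0,
                   surface_offsets_mm = offs,
                   density_scale = 1 + dens_pct / 100,
                   hu_noise_sd = 20,
                   seed = seed + 7919L * patient + match(side, sides))
    }
  }
  metadata <- data.frame(
    patient = seq_len(n_patients),
    sex = ifelse(seq_len(n_patients) %% 3 == 0, "F", "M"),
    dysmorphism = ifelse(seq_len(n_patients) > ceiling(5 * n_patients / 6),
                         "II", "III"))
  meas_rows <- list(); truth_rows <- list(); pairs <- list()
  for (i in seq_len(n_patients)) {
    for (s in sides) {
      spec_i <- base_spec
      spec_i$side <- s
      spec_i$seed <- seed + 101L * i + 13L * match(s, sides)
      rem <- with_seed(seed + 1009L * i + match(s, sides),
                       remodel_sampler(i, s))
      ph <- generate_phantom(spec_i, with_mesh = compute_surfaces)
      pair <- apply_remodeling(ph, rem)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        patient = i, side = s,
        height_delta_mm = pair$truth$height_delta_mm,
        axis_delta_deg = pair$truth$axis_delta_deg,
        intercondylar_delta_deg = pair$truth$intercondylar_delta_deg,
        density_delta_pct = pair$truth$density_delta_pct,
        t(pair$truth$surface_offsets_mm))
      if (measure) {
        cmp <- compare_condyle_studies(pair$pre, pair$post,
                                       compute_surfaces = compute_surfaces)
        d <- cmp$deltas
        add <- function(variable, delta, side_ = s, pct = NA_real_) {
          meas_rows[[length(meas_rows) + 1]] <<- data.frame(
            patient = i, side = side_, variable = variable, delta = delta,
            delta_pct = pct)
        }
        add("height_mm", d$height_mm, pct = d$height_pct)
        add("axis_deg", d$axis_deg)
        if (s == "left") add("intercondylar_deg", d$intercondylar_deg, "n/a")
        add("volume_mm3", d$volume_mm3, "n/a", pct = d$volume_pct)
        add("density_hu", d$density_hu, pct = d$density_pct)
        if (compute_surfaces) {
          for (surf in SURFACE_LABELS)
            add(paste0("surface_", surf),
                d$surfaces$mean_mm[d$surfaces$surface == surf])
        }
      }
      if (keep_pairs) pairs[[paste(i, s)]] <- pair
    }
  }
  structure(list(
    measurements = if (measure) do.call(rbind, meas_rows) else NULL,
    truth = do.call(rbind, truth_rows),
    metadata = metadata,
    pairs = if (keep_pairs) pairs else NULL,
    seed = seed),
    class = "phantom_cohort")
}
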