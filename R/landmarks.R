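# Named anatomical landmarks and the per-condyle study container.

LANDMARK_NAMES <- c(
  "condyle_apex",            # highest point of the condylar head
  "gonion_lowest",           # lowest point of the mandibular angle
  "condyle_center_left",     # centre of maximum transverse diameter, left
  "condyle_center_right",    # centre of maximum transverse diameter, right
  "foramen_magnum_anterior", # vertex of the intercondylar angle
  "transverse_diameter_1",   # endpoints of the maximum transverse diameter
  "transverse_diameter_2",
  "ramus_axis_1",            # two points on the ramus major axis
  "ramus_axis_2")

#' Named landmark set
#'
#' Named anatomical points in mm (patient frame). The canonical names used by
#' the measurement operations are: `condyle_apex`, `gonion_lowest`,
#' `condyle_center_left`, `condyle_center_right`, `foramen_magnum_anterior`,
#' `transverse_diameter_1`/`_2` (endpoints of the maximum transverse condylar
#' diameter) and `ramus_axis_1`/`_2` (two points on the ramus major axis).
#' Unknown names are kept but flagged with a message; missing names only
#' error when a measurement that needs them is requested.
#'
#' @param points a named list of length-3 numeric vectors, or an n x 3
#'   matrix with rownames.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points) {
  if (is.matrix(points)) {
    nm <- rownames(points)
    points <- lapply(seq_len(nrow(points)), function(i) as.numeric(points[i, ]))
    names(points) <- nm
  }
  nm <- names(points)
  if (is.null(nm) || any(nm == ""))
    stop("all landmarks must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate landmark name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  points <- lapply(points, as.numeric)
  bad <- vapply(points, function(p) length(p) != 3 || any(!is.finite(p)),
                logical(1))
  if (any(bad))
    stop("landmark coordinates must be three finite numbers: ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  unknown <- setdiff(nm, LANDMARK_NAMES)
  if (length(unknown))
    message("unrecognised landmark name(s) kept: ",
            paste(unknown, collapse = ", "))
  structure(list(points = points), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points: %s\n", length(x$points),
              paste(names(x$points), collapse = ", ")))
  invisible(x)
}

# Fetch a landmark, erroring with the canonical message at measurement time.
get_landmark <- function(landmarks, name) {
  stopifnot(inherits(landmarks, "landmark_set"))
  p <- landmarks$points[[name]]
  if (is.null(p)) stop("landmark missing: ", name, call. = FALSE)
  p
}

#' Read / write landmarks as JSON
#'
#' The on-disk format is a JSON object mapping landmark names to `[x, y, z]`
#' mm coordinates.
#'
#' @param path a `.json` file.
#' @param landmarks a [landmark_set()].
#' @return `read_landmarks()` returns a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(obj) && !is.matrix(obj))
    stop("landmark JSON must map names to [x, y, z]", call. = FALSE)
  landmark_set(lapply(obj, as.numeric))
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(landmarks$points, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Apply a rigid transform to a landmark set
#'
#' @param landmarks a [landmark_set()].
#' @param transform a [rigid_transform()].
#' @return The transformed [landmark_set()].
#' @export
transform_landmarks <- function(landmarks, transform) {
  landmark_set(lapply(landmarks$points,
                      function(p) transform_points(transform, p)))
}

#' One condyle at one timepoint
#'
#' Bundles the voxel volume, its segmentation mask, the surface mesh and the
#' landmark set for one condyle at one imaging timepoint. The mask must be
#' congruent with the volume; mesh and landmarks are expressed in the
#' volume's physical frame.
#'
#' @param side `"left"` or `"right"`.
#' @param timepoint `"T0"` (baseline) or `"T1"` (follow-up).
#' @param volume a [ct_volume()].
#' @param mask a [ct_mask()] congruent with `volume`.
#' @param mesh a [surface_mesh()].
#' @param landmarks a [landmark_set()].
#' @return An object of class `condyle_study`.
#' @export
condyle_study <- function(side, timepoint, volume, mask, mesh, landmarks) {
  side <- match.arg(side, c("left", "right"))
  timepoint <- match.arg(timepoint, c("T0", "T1"))
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "ct_mask"),
            inherits(mesh, "surface_mesh"), inherits(landmarks, "landmark_set"))
  check_congruent(volume, mask)
  structure(list(side = side, timepoint = timepoint, volume = volume,
                 mask = mask, mesh = mesh, landmarks = landmarks),
            class = "condyle_study")
}

#' @export
print.condyle_study <- function(x, ...) {
  cat(sprintf("<condyle_study> %s condyle at %s\n", x$side, x$timepoint))
  print(x$volume); print(x$mask); print(x$mesh); print(x$landmarks)
  invisible(x)
}

#' Condylar local frame from landmarks
#'
#' Builds the orthonormal local frame used for surface parcellation and for
#' initialising registration: origin at the midpoint of the transverse
#' diameter (condylar head centre), `superior` along the ramus major axis,
#' `medial` towards the midline (side-dependent), `anterior` completing the
#' right-handed frame.
#'
#' @param landmarks a [landmark_set()] with `transverse_diameter_1/2` and
#'   `ramus_axis_1/2`.
#' @param side `"left"` or `"right"` — which condyle the landmarks describe.
#' @return A list with `origin`, `superior`, `anterior`, `medial` (unit
#'   vectors, mm).
#' @export
condylar_frame <- function(landmarks, side = c("left", "right")) {
  side <- match.arg(side)
  t1 <- get_landmark(landmarks, "transverse_diameter_1")
  t2 <- get_landmark(landmarks, "transverse_diameter_2")
  r1 <- get_landmark(landmarks, "ramus_axis_1")
  r2 <- get_landmark(landmarks, "ramus_axis_2")
  origin <- (t1 + t2) / 2
  superior <- unit_vector(r2 - r1, "ramus axis")
  if (superior[3] < 0) superior <- -superior
  ml <- t2 - t1
  ml <- ml - sum(ml * superior) * superior  # orthogonalise against superior
  ml <- unit_vector(ml, "transverse diameter")
  anterior <- unit_vector(cross3(superior, ml), "anterior axis")
  if (anterior[2] > 0) anterior <- -anterior  # LPS +y is posterior
  medial <- cross3(superior, anterior)
  # medial points toward the midline: -x for a left condyle (+x is left in
  # LPS), +x for a right condyle
  med_sign <- if (side == "left") -1 else 1
  if (medial[1] * med_sign < 0) medial <- -medial
  list(origin = origin, superior = superior, anterior = anterior,
       medial = medial)
}
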