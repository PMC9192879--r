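# Landmark-based linear and angular measurements.

new_measurement <- function(kind, value, unit, points = NULL, plane = "3D") {
  structure(list(kind = kind, value = value, unit = unit, points = points,
                 plane = plane),
            class = "condylar_measurement")
}

#' @export
print.condylar_measurement <- function(x, ...) {
  cat(sprintf("<%s> %.1f %s (%s)\n", x$kind, x$value, x$unit, x$plane))
  invisible(x)
}

#' Ramus height
#'
#' Distance in mm from the highest point of the condylar head
#' (`condyle_apex`) to the lowest point of the mandibular angle
#' (`gonion_lowest`), the standard two-point operationalisation of the
#' tangent-line ramus height used to monitor condylar resorption.
#'
#' @param landmarks a [landmark_set()] for one condyle.
#' @param side optional side tag carried through for reporting.
#' @return A `condylar_measurement` with `value` in mm (>= 0) and the two
#'   defining points retained for audit.
#' @examples
#' lm <- landmark_set(list(condyle_apex = c(0, 0, 50),
#'                         gonion_lowest = c(0, 0, 0)))
#' ramus_height(lm)$value  # 50
#' @export
ramus_height <- function(landmarks, side = NULL) {
  apex <- get_landmark(landmarks, "condyle_apex")
  gonion <- get_landmark(landmarks, "gonion_lowest")
  m <- new_measurement("ramus_height", vec_norm(apex - gonion), "mm",
                       points = list(condyle_apex = apex,
                                     gonion_lowest = gonion))
  m$side <- side
  m
}

#' Intercondylar angle
#'
#' Angle at the anterior border of the foramen magnum (vertex) subtended by
#' the centres of the maximum transverse diameter of the left and right
#' condylar heads.
#'
#' @param landmarks a [landmark_set()] with `condyle_center_left`,
#'   `condyle_center_right` and `foramen_magnum_anterior`.
#' @return A `condylar_measurement` with `value` in degrees, in \[0, 180\].
#' @export
intercondylar_angle <- function(landmarks) {
  a <- get_landmark(landmarks, "condyle_center_left")
  b <- get_landmark(landmarks, "condyle_center_right")
  v <- get_landmark(landmarks, "foramen_magnum_anterior")
  m <- new_measurement("intercondylar_angle", angle_between(a - v, b - v),
                       "deg",
                       points = list(condyle_center_left = a,
                                     condyle_center_right = b,
                                     foramen_magnum_anterior = v))
  m
}

#' Condylar axis inclination
#'
#' Coronal-plane angle between the maximum transverse diameter line (line A)
#' and the ramus major axis (line B). Both lines are orthogonally projected
#' onto the coronal (frontal) plane — the plane orthogonal to the
#' anterior-posterior axis of the patient frame — before measuring, matching
#' a measurement drawn on coronal slices.
#'
#' @param landmarks a [landmark_set()] with `transverse_diameter_1/2` and
#'   `ramus_axis_1/2`; alternatively pass the four points explicitly.
#' @param transverse,ramus_axis optional 2 x 3 matrices (one point per row)
#'   overriding the landmark lookup.
#' @return A `condylar_measurement` with `value` in degrees, in \[0, 180).
#' @export
condylar_axis_inclination <- function(landmarks = NULL, transverse = NULL,
                                      ramus_axis = NULL) {
  if (is.null(transverse)) {
    transverse <- rbind(get_landmark(landmarks, "transverse_diameter_1"),
                        get_landmark(landmarks, "transverse_diameter_2"))
  }
  if (is.null(ramus_axis)) {
    ramus_axis <- rbind(get_landmark(landmarks, "ramus_axis_1"),
                        get_landmark(landmarks, "ramus_axis_2"))
  }
  a <- transverse[2, ] - transverse[1, ]
  b <- ramus_axis[2, ] - ramus_axis[1, ]
  # coronal projection: drop the anterior-posterior (y) component
  a[2] <- 0
  b[2] <- 0
  if (vec_norm(a) < 1e-9 || vec_norm(b) < 1e-9)
    stop("degenerate geometry: line orthogonal to the coronal plane",
         call. = FALSE)
  ang <- angle_between(a, b)
  if (ang >= 180) ang <- 0
  new_measurement("condylar_axis_inclination", ang, "deg",
                  points = list(transverse = transverse,
                                ramus_axis = ramus_axis),
                  plane = "coronal-projected")
}

#' Pre/post change of a measurement
#'
#' @param t0,t1 baseline and follow-up values; either numbers or
#'   `condylar_measurement` objects of the same kind.
#' @param as_percent if TRUE, return `100 * (t1 - t0) / t0` instead of the
#'   absolute difference.
#' @return A signed scalar (mm, degrees, or percent).
#' @examples
#' measurement_delta(524.6, 406.5, as_percent = TRUE)  # -22.5
#' @export
measurement_delta <- function(t0, t1, as_percent = FALSE) {
  if (inherits(t0, "condylar_measurement")) {
    if (inherits(t1, "condylar_measurement") && !identical(t0$kind, t1$kind))
      stop("cannot compare measurements of different kinds", call. = FALSE)
    t0 <- t0$value
  }
  if (inherits(t1, "condylar_measurement")) t1 <- t1$value
  if (!is.finite(t0) || !is.finite(t1))
    stop("measurements must be finite", call. = FALSE)
  if (as_percent) {
    if (t0 == 0) stop("percent change undefined: baseline is zero",
                      call. = FALSE)
    100 * (t1 - t0) / t0
  } else {
    t1 - t0
  }
}

#' Condylar resorption flag (Hoppenreijs criterion)
#'
#' Flags pathological condylar resorption: a ramus height reduction greater
#' than 6% of the pre-surgical value.
#'
#' @param height_percent_delta percent change of ramus height
#'   (`100 * (T1 - T0) / T0`).
#' @return TRUE iff the loss strictly exceeds 6% (i.e. delta < -6).
#' @examples
#' classify_resorption(-3.89)  # FALSE
#' classify_resorption(-6.01)  # TRUE
#' @export
classify_resorption <- function(height_percent_delta) {
  if (any(!is.finite(height_percent_delta)))
    stop("percent delta must be finite", call. = FALSE)
  height_percent_delta < -6.0
}
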