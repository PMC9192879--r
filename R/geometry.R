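# Small 3D geometry helpers shared across modules. All vectors are length-3
# numerics in mm (LPS patient frame).

vec_norm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v, what = "vector") {
  n <- vec_norm(v)
  if (!is.finite(n) || n < 1e-12)
    stop("degenerate geometry: zero-length ", what, call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle between two vectors in degrees, in [0, 180].
angle_between <- function(a, b) {
  ua <- unit_vector(a, "direction")
  ub <- unit_vector(b, "direction")
  # atan2 form is numerically stable near 0 and 180 degrees
  atan2(vec_norm(cross3(ua, ub)), sum(ua * ub)) * 180 / pi
}

# Rotation matrix about an arbitrary unit axis (Rodrigues), angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit_vector(axis, "rotation axis")
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid transformation in 3D
#'
#' A proper rigid transform (rotation + translation, no scaling), used to map
#' a moving surface into the frame of a fixed surface after registration.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric, millimetres.
#' @return An object of class `rigid_transform`.
#' @seealso [register_rigid()], [transform_points()]
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# Rotation magnitude in degrees from a rotation matrix.
rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points an n x 3 matrix (or length-3 vector) of coordinates in mm.
#' @return Transformed coordinates with the same shape as the input.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else as.matrix(points)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  if (single) drop(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first and then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

# Random rotation matrix (uniform via QR of Gaussian), used by property tests
# and the cohort generator. Relies on the caller having seeded the RNG.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Least-squares rigid alignment (Kabsch): finds rigid_transform minimising
# ||R p + t - q||^2 over paired rows of p and q.
kabsch <- function(p, q) {
  pm <- colMeans(p); qm <- colMeans(q)
  H <- crossprod(sweep(p, 2, pm), sweep(q, 2, qm))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, qm - as.numeric(R %*% pm))
}
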