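# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# default phantom at the working test resolution
test_phantom <- function() {
  cached("phantom05", generate_phantom(phantom_spec(spacing_mm = 0.5)))
}

# strongly asymmetric closed mesh for registration tests: a bumpy sphere
# (radius ~10 mm) with deterministic lobes that pin down all six degrees of
# freedom
bumpy_mesh <- function(subdivisions = 4) {
  cached(paste0("bumpy", subdivisions), {
    s <- mesh_icosphere(1, c(0, 0, 0), subdivisions)
    v <- s$vertices
    th <- atan2(v[, 2], v[, 1])
    ph <- acos(pmin(1, pmax(-1, v[, 3])))
    r <- 10 * (1 + 0.15 * sin(3 * th) * sin(2 * ph) +
                 0.1 * cos(2 * th + 1) * cos(3 * ph))
    surface_mesh(v * r, s$faces)
  })
}

# canonical orthonormal condylar frame for partition tests
test_frame <- function(origin = c(0, 0, 0)) {
  list(origin = origin, superior = c(0, 0, 1), anterior = c(0, -1, 0),
       medial = c(-1, 0, 0))
}

rot_axis <- condylometry:::rotation_about_axis
rot_angle <- condylometry:::rotation_angle_deg

# one reusable landmark set with simple geometry
simple_landmarks <- function() {
  landmark_set(list(
    condyle_apex = c(0, 0, 50),
    gonion_lowest = c(0, 0, 0),
    condyle_center_left = c(40, -5, 45),
    condyle_center_right = c(-40, -5, 45),
    foramen_magnum_anterior = c(0, 15, 30),
    transverse_diameter_1 = c(-10, 0, 45),
    transverse_diameter_2 = c(10, 0, 45),
    ramus_axis_1 = c(0, 0, 5),
    ramus_axis_2 = c(0, 0, 45)))
}

sort_rows <- function(m) m[order(m[, 1], m[, 2], m[, 3]), ]
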