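# ROI clipping, voxel volumetry and densitometry against analytic oracles.

# digitise a solid of revolution: inside(coords) -> logical
digitize <- function(inside, lo, hi, spacing) {
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  xs <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  ys <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  zs <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  coords <- cbind(rep(xs, times = dims[2] * dims[3]),
                  rep(rep(ys, each = dims[1]), times = dims[3]),
                  rep(zs, each = dims[1] * dims[2]))
  ct_mask(array(inside(coords), dims), spacing = rep(spacing, 3),
          origin = lo)
}

sphere_mask <- function(r, spacing) {
  digitize(function(p) rowSums(p^2) <= r^2,
           rep(-r - 1, 3), rep(r + 1, 3), spacing)
}

cylinder_mask <- function(r, len, spacing) {
  digitize(function(p) p[, 1]^2 + p[, 2]^2 <= r^2 &
             p[, 3] >= 0 & p[, 3] <= len,
           c(-r - 1, -r - 1, -1), c(r + 1, r + 1, len + 1), spacing)
}

test_that("mask volume counts voxels times voxel volume", {
  m <- ct_mask(array(c(rep(TRUE, 1000), rep(FALSE, 24 * 1000 - 1000)),
                     c(10, 10, 240)), spacing = c(1, 1, 1))
  expect_equal(mask_volume(m), 1000)
  empty <- ct_mask(array(FALSE, c(3, 3, 3)), spacing = c(1, 1, 1))
  expect_equal(mask_volume(empty), 0)
})

test_that("digitised sphere volume matches the analytic value within 2%, error halving with spacing", {
  r <- 6
  analytic <- 4 / 3 * pi * r^3
  v_050 <- mask_volume(sphere_mask(r, 0.5))
  v_025 <- mask_volume(sphere_mask(r, 0.25))
  expect_lt(abs(v_025 - analytic) / analytic, 0.02)
  err_050 <- abs(v_050 - analytic)
  err_025 <- abs(v_025 - analytic)
  expect_lt(err_025, err_050 / 2 + 1e-9)
})

test_that("condylar ROI is the half-open 15 mm slab below the apex", {
  m <- cylinder_mask(5, 40, 0.25)
  apex <- c(0, 0, 40)
  roi <- clip_condylar_roi(m, axis = c(0, 0, -1), apex = apex, depth = 15)
  expect_lt(abs(mask_volume(roi) - pi * 25 * 15) / (pi * 25 * 15), 0.02)
  # subset of the source mask
  expect_true(all(m$data[roi$data]))
  # no-op slab
  roi_inf <- clip_condylar_roi(m, c(0, 0, -1), apex, depth = Inf)
  expect_identical(roi_inf$data, m$data)
  expect_error(clip_condylar_roi(m, c(0, 0, -1), apex, depth = 0),
               "depth")
  expect_error(clip_condylar_roi(m, c(0, 0, -1), c(100, 100, 100)),
               "apex outside")
  expect_error(clip_condylar_roi(m, c(0, 0, -1), c(0, 0, -0.8), depth = 0.01),
               "ROI empty")
})

test_that("enlarging the ROI depth never decreases its volume", {
  m <- cylinder_mask(5, 40, 0.5)
  vols <- vapply(c(2, 5, 10, 15, 25, 50),
                 function(d) mask_volume(clip_condylar_roi(
                   m, c(0, 0, -1), c(0, 0, 40), depth = d)), numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("ROI volume and density are exactly equivariant under 90-degree rotations", {
  ph <- test_phantom()
  mask <- ph$study$mask
  vol <- ph$study$volume
  apex <- ph$study$landmarks$points$condyle_apex
  axis <- -ph$frame$superior
  roi <- clip_condylar_roi(mask, axis, apex, 15)
  v0 <- mask_volume(roi)
  hu0 <- mean_density(vol, roi)
  # rotate everything +90 degrees about z: (x, y, z) -> (-y, x, z)
  rot_arr <- function(a) {
    d <- dim(a)
    aperm(a, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  sp <- mask$spacing
  n <- dim(mask$data)
  # new origin after mapping voxel centres through the rotation
  o <- mask$origin
  new_origin <- c(-(o[2] + (n[2] - 1) * sp[2]), o[1], o[3])
  mask_r <- ct_mask(rot_arr(mask$data), spacing = sp[c(2, 1, 3)],
                    origin = new_origin)
  vol_r <- ct_volume(rot_arr(vol$data), spacing = sp[c(2, 1, 3)],
                     origin = new_origin)
  R <- rot_axis(c(0, 0, 1), 90)
  apex_r <- as.numeric(R %*% apex)
  axis_r <- as.numeric(R %*% axis)
  roi_r <- clip_condylar_roi(mask_r, axis_r, apex_r, 15)
  expect_identical(sum(roi_r$data), sum(roi$data))
  expect_equal(mean_density(vol_r, roi_r), hu0)
  expect_equal(mask_volume(roi_r), v0)
})

test_that("mean density averages HU over the mask", {
  a <- array(500, c(4, 4, 4))
  vol <- ct_volume(a, spacing = c(1, 1, 1))
  m <- ct_mask(array(TRUE, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_equal(mean_density(vol, m), 500)
  a[1:2, , ] <- 400
  a[3:4, , ] <- 600
  expect_equal(mean_density(ct_volume(a, spacing = c(1, 1, 1)), m), 500)
  empty <- ct_mask(array(FALSE, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_error(mean_density(vol, empty), "empty")
  small <- ct_mask(array(TRUE, c(2, 2, 2)), spacing = c(1, 1, 1))
  expect_error(mean_density(vol, small), "shape")
})

test_that("phantom trabecular core recovers the prescribed HU distribution", {
  # >= 1e5 core voxels at 0.3 mm spacing; shell excluded by construction
  ph <- cached("phantom03_novol",
               generate_phantom(phantom_spec(spacing_mm = 0.3, seed = 7),
                                with_mesh = FALSE))
  expect_gt(sum(ph$core_mask$data), 1e5)
  core_mean <- mean_density(ph$study$volume, ph$core_mask)
  expect_lt(abs(core_mean - 550), 1)
})

test_that("density change is the percent change of mean HU", {
  expect_equal(round(density_change(524.6, 406.5), 1), -22.5)
  expect_equal(round(density_change(455.80, 297.20), 1), -34.8)
  expect_equal(density_change(613, 613), 0)
  expect_error(density_change(0, 10), "zero")
  pre <- structure(list(mean_hu = 500), class = "density_record")
  post <- structure(list(mean_hu = 400), class = "density_record")
  expect_equal(density_change(pre, post), -20)
})
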