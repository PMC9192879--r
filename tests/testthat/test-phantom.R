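# Synthetic phantom: determinism, ground truth, prescribed-change recovery.

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantom_spec(spacing_mm = 1.2, shell_thickness_mm = 1.5, seed = 17)
  a <- generate_phantom(spec, with_mesh = FALSE)
  b <- generate_phantom(spec, with_mesh = FALSE)
  expect_identical(a$study$volume$data, b$study$volume$data)
  expect_identical(a$study$mask$data, b$study$mask$data)
  expect_equal(a$truth, b$truth)
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(ramus_length_mm = -5), "positive")
  expect_error(phantom_spec(cortical_hu = 400, trabecular_mean_hu = 550),
               "cortical")
  expect_error(phantom_spec(spacing_mm = 2, shell_thickness_mm = 1.5),
               "too coarse")
  expect_error(remodel_spec(surface_offsets_mm = c(anterior = 3)), "2 mm")
  expect_error(remodel_spec(density_scale = 0), "density scale")
  expect_error(remodel_spec(surface_offsets_mm = c(front = 1)),
               "unknown surface label")
})

test_that("prescribed ramus length is recovered from the landmarks and the mesh", {
  ph <- test_phantom()
  expect_equal(ph$truth$height_mm, 62)
  m <- measure_condyle(ph$study)
  sp <- ph$spec$spacing_mm
  expect_lt(abs(m$height_mm - 62), 2 * sp)
  # independent mesh-based check: topmost mesh point vs apex, lowest vs gonion
  h <- ph$study$mesh$vertices %*% ph$frame$superior
  apex_h <- as.numeric(ph$study$landmarks$points$condyle_apex %*%
                         ph$frame$superior)
  expect_lt(abs(max(h) - apex_h), 2 * sp)
})

test_that("mesh-derived apex error shrinks with voxel spacing", {
  err <- vapply(c(0.8, 0.4), function(sp) {
    ph <- generate_phantom(phantom_spec(spacing_mm = sp, seed = 19))
    h <- ph$study$mesh$vertices %*% ph$frame$superior
    apex_h <- as.numeric(ph$study$landmarks$points$condyle_apex %*%
                           ph$frame$superior)
    abs(max(h) - apex_h)
  }, numeric(1))
  expect_lt(err[1], 2 * 0.8)
  expect_lt(err[2], 2 * 0.4)
  expect_lte(err[2], err[1] + 0.05)
})

test_that("an all-zero remodel measures all six deltas at zero", {
  ph <- test_phantom()
  pair <- apply_remodeling(ph, remodel_spec(seed = 23))
  cmp <- compare_condyle_studies(pair$pre, pair$post)
  sp <- ph$spec$spacing_mm
  expect_lt(abs(cmp$deltas$height_mm), 2 * sp)
  expect_lt(abs(cmp$deltas$axis_deg), 0.5)
  expect_lt(abs(cmp$deltas$intercondylar_deg), 0.5)
  expect_equal(cmp$deltas$volume_mm3, 0)
  expect_lt(abs(cmp$deltas$density_pct), 1)
  expect_lt(max(abs(cmp$deltas$surfaces$mean_mm)), 0.05)
})

test_that("density scaling is recovered within one percentage point", {
  ph <- test_phantom()
  pair <- apply_remodeling(ph, remodel_spec(density_scale = 0.7,
                                            hu_noise_sd = 20, seed = 24))
  expect_lt(abs(pair$truth$density_delta_pct - (-30)), 0.5)
  cmp <- compare_condyle_studies(pair$pre, pair$post,
                                 compute_surfaces = FALSE)
  expect_lt(abs(cmp$deltas$density_pct - (-30)), 1)
})

test_that("prescribed rotations and surface offsets are recovered by the pipeline", {
  ph <- test_phantom()
  rem <- remodel_spec(height_delta_mm = -1.5, axis_rotation_deg = 6.9,
                      intercondylar_delta_deg = -10.8,
                      surface_offsets_mm = c(anterior = 0.2,
                                             posterior = -0.2),
                      seed = 25)
  pair <- apply_remodeling(ph, rem)
  # landmark channels realise the prescription exactly
  expect_equal(pair$truth$height_delta_mm, -1.5, tolerance = 1e-9)
  expect_equal(abs(pair$truth$axis_delta_deg), 6.9, tolerance = 1e-9)
  expect_equal(pair$truth$intercondylar_delta_deg, -10.8, tolerance = 1e-6)
  cmp <- compare_condyle_studies(pair$pre, pair$post)
  sp <- ph$spec$spacing_mm
  expect_lt(abs(cmp$deltas$height_mm - (-1.5)), 2 * sp)
  expect_lt(abs(abs(cmp$deltas$axis_deg) - 6.9), 0.5)
  expect_lt(abs(cmp$deltas$intercondylar_deg - (-10.8)), 0.5)
  surf <- cmp$deltas$surfaces
  expect_lt(abs(surf$mean_mm[surf$surface == "anterior"] - 0.2), 0.05)
  expect_lt(abs(surf$mean_mm[surf$surface == "posterior"] + 0.2), 0.05)
  for (s in c("medial", "lateral", "superior"))
    expect_lt(abs(surf$mean_mm[surf$surface == s]), 0.05)
})

test_that("the pipeline recovers offsets through an arbitrary pose change", {
  ph <- test_phantom()
  rem <- remodel_spec(surface_offsets_mm = c(anterior = 0.3), seed = 26)
  pair <- apply_remodeling(ph, rem)
  # simulate a different scan pose at T1: move mesh and landmarks together
  # (rotation about the condylar head centre, so the apex stays inside the
  # volume and the region of interest remains measurable)
  Rp <- rot_axis(c(0.2, 1, 0.5), 8)
  O <- ph$frame$origin
  pose <- rigid_transform(Rp, O - as.numeric(Rp %*% O) + c(1, -1, 0.5))
  post <- pair$post
  post$mesh <- transform_mesh(post$mesh, pose)
  post$landmarks <- transform_landmarks(post$landmarks, pose)
  cmp <- compare_condyle_studies(pair$pre, post, compute_surfaces = TRUE)
  surf <- cmp$deltas$surfaces
  expect_lt(abs(surf$mean_mm[surf$surface == "anterior"] - 0.3), 0.05)
  expect_lt(abs(surf$mean_mm[surf$surface == "superior"]), 0.05)
})

test_that("cohort generation is deterministic and recovers its prescriptions", {
  co1 <- generate_cohort(n_patients = 3,
                         base_spec = phantom_spec(spacing_mm = 0.8),
                         seed = 5, measure = FALSE)
  co2 <- generate_cohort(n_patients = 3,
                         base_spec = phantom_spec(spacing_mm = 0.8),
                         seed = 5, measure = FALSE)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$metadata$sex, c("M", "M", "F"))

  co <- generate_cohort(n_patients = 4,
                        base_spec = phantom_spec(spacing_mm = 0.6),
                        seed = 6, measure = TRUE)
  m <- co$measurements
  tr <- co$truth
  for (i in 1:4) {
    for (s in c("right", "left")) {
      got <- m$delta[m$patient == i & m$side == s & m$variable == "height_mm"]
      want <- tr$height_delta_mm[tr$patient == i & tr$side == s]
      expect_lt(abs(got - want), 2 * 0.6)
      got_d <- m$delta_pct[m$patient == i & m$side == s &
                             m$variable == "density_hu"]
      want_d <- tr$density_delta_pct[tr$patient == i & tr$side == s]
      expect_lt(abs(got_d - want_d), 1.5)
    }
  }
})
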