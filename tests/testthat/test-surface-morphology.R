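# Signed distances, anatomical parcellation, per-region summaries, colour map.

test_that("identical meshes give a zero distance map", {
  mesh <- mesh_icosphere(10, c(0, 0, 0), 3)
  dm <- signed_distances(mesh, mesh)
  expect_lt(max(abs(dm$distance)), 1e-9)
})

test_that("a uniformly inflated sphere reads +0.5 mm everywhere", {
  # subdivision 4 keeps the facet sag of the target well below the 1e-3
  # tolerance at this radius
  s1 <- mesh_icosphere(10, c(1, 2, 3), 4)
  s2 <- mesh_icosphere(10.5, c(1, 2, 3), 4)
  dm <- signed_distances(s1, s2)
  expect_lt(max(abs(dm$distance - 0.5)), 1e-3)
  # sign convention: shrinking reads negative (resorption)
  dm_in <- signed_distances(s2, s1)
  expect_lt(max(abs(dm_in$distance + 0.5)), 1e-3)
})

test_that("partition labels follow the frame directions and cover every vertex", {
  fr <- test_frame()
  v <- rbind(c(0, 0, 5),      # straight up -> superior
             c(0, -5, 0),     # along anterior axis at the equator
             c(0, 5, 0),      # posterior
             c(-5, 0, 0),     # medial
             c(5, 0, 0),      # lateral
             c(0, -4, 5))     # ~39 degrees off superior: inside the cone
  mesh <- surface_mesh(v, matrix(c(1L, 2L, 3L), 1))
  lab <- partition_condylar_surface(mesh, fr)
  expect_equal(as.character(lab),
               c("superior", "anterior", "posterior", "medial", "lateral",
                 "superior"))
  sphere <- mesh_icosphere(8, c(0, 0, 0), 3)
  lab_s <- partition_condylar_surface(sphere, fr)
  expect_false(anyNA(lab_s))
  expect_setequal(as.character(unique(lab_s)),
                  c("anterior", "posterior", "medial", "lateral", "superior"))
  expect_error(partition_condylar_surface(sphere, list(origin = c(0, 0, 0),
                                                       superior = c(0, 0, 0),
                                                       anterior = c(0, 1, 0),
                                                       medial = c(1, 0, 0))),
               "degenerate frame")
})

test_that("the partition is equivariant under joint rigid motion", {
  set.seed(41)
  # vertices in generic position: the raw icosphere has vertices exactly on
  # the 45-degree label boundaries, whose side flips under round-off; a
  # generic pre-rotation moves every vertex well clear of the boundaries
  base_s <- mesh_icosphere(8, c(0, 0, 0), 3)
  vg <- base_s$vertices %*% t(rot_axis(c(1, 2, 3), 7.3))
  sphere <- surface_mesh(sweep(vg, 2, c(2, -1, 4), "+"), base_s$faces)
  fr <- test_frame(origin = c(2, -1, 4))
  base <- table(partition_condylar_surface(sphere, fr))
  for (i in 1:10) {
    R <- condylometry:::random_rotation()
    t <- rnorm(3, 0, 10)
    tr <- rigid_transform(R, t)
    mesh_r <- transform_mesh(sphere, tr)
    fr_r <- list(origin = transform_points(tr, fr$origin),
                 superior = as.numeric(R %*% fr$superior),
                 anterior = as.numeric(R %*% fr$anterior),
                 medial = as.numeric(R %*% fr$medial))
    expect_identical(table(partition_condylar_surface(mesh_r, fr_r)), base)
  }
})

test_that("per-region means summarise the distance map by label", {
  sphere <- mesh_icosphere(8, c(0, 0, 0), 3)
  labels <- partition_condylar_surface(sphere, test_frame())
  n <- nrow(sphere$vertices)
  dm <- structure(list(distance = rep(0.5, n), vertex = seq_len(n),
                       reference = "T0"), class = "distance_map")
  pm <- per_surface_means(dm, labels)
  expect_equal(pm$mean_mm, rep(0.5, 5))
  expect_identical(sum(pm$n_vertices), n)
  # an absent label is reported as missing, not dropped
  dm_sub <- structure(list(distance = rep(0.2, sum(labels == "superior")),
                           vertex = which(labels == "superior"),
                           reference = "T0"), class = "distance_map")
  pm2 <- per_surface_means(dm_sub, labels)
  expect_true(is.na(pm2$mean_mm[pm2$surface == "anterior"]))
  expect_equal(pm2$mean_mm[pm2$surface == "superior"], 0.2)
})

test_that("swapping reference and target flips per-region mean signs", {
  ph <- test_phantom()
  rem <- remodel_spec(surface_offsets_mm = c(anterior = 0.2,
                                             posterior = -0.2), seed = 6)
  pair <- apply_remodeling(ph, rem)
  labels <- partition_condylar_surface(pair$pre$mesh, ph$frame)
  fwd <- per_surface_means(signed_distances(pair$pre$mesh, pair$post$mesh),
                           labels)
  labels1 <- partition_condylar_surface(pair$post$mesh, ph$frame)
  rev <- per_surface_means(signed_distances(pair$post$mesh, pair$pre$mesh),
                           labels1)
  for (s in c("anterior", "posterior")) {
    a <- fwd$mean_mm[fwd$surface == s]
    b <- rev$mean_mm[rev$surface == s]
    expect_lt(abs(a + b), 0.05)
  }
})

test_that("colour-map PLY export writes diverging colours and round-trips scalars", {
  mesh <- mesh_icosphere(5, c(0, 0, 0), 2)
  n <- nrow(mesh$vertices)
  d <- rep(0, n)
  d[1] <- 1
  d[2] <- -1
  dm <- structure(list(distance = d, vertex = seq_len(n), reference = "T0"),
                  class = "distance_map")
  f <- withr::local_tempfile(fileext = ".ply")
  export_colormap(mesh, dm, f, dmax = 1)
  back <- read_mesh(f)
  expect_equal(back$scalars, d)
  cols <- attr(back, "ply_colors")
  expect_equal(unname(cols[1, ]), c(255, 0, 0))    # saturated red
  expect_equal(unname(cols[2, ]), c(0, 0, 255))    # saturated blue
  expect_equal(unname(cols[3, ]), c(255, 255, 255))  # neutral midpoint
})
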