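# Readers/writers and the spatial data model.

test_that("ct_volume validates its invariants", {
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "strictly positive")
  expect_error(ct_volume(array(NaN, c(2, 2, 2)), spacing = c(1, 1, 1)),
               "finite")
  expect_warning(ct_volume(array(9000, c(2, 2, 2)), spacing = c(1, 1, 1)),
                 "plausible HU range")
  vol <- ct_volume(array(0, c(2, 3, 4)), spacing = c(0.5, 0.5, 1))
  expect_equal(voxel_volume(vol), 0.25)
})

test_that("voxel/world conversion is consistent: a landmark at a voxel centre maps back", {
  vol <- ct_volume(array(0, c(5, 6, 7)), spacing = c(0.5, 0.4, 1.1),
                   origin = c(-4, 3, 9))
  idx <- rbind(c(1, 1, 1), c(3, 5, 2), c(5, 6, 7))
  expect_equal(world_to_voxel(vol, voxel_to_world(vol, idx)), idx)
  expect_equal(voxel_to_world(vol, c(1, 1, 1)), vol$origin)
})

test_that("NIfTI volumes round-trip exactly", {
  set.seed(11)
  vol <- ct_volume(array(round(rnorm(6 * 5 * 4, 300, 200)), c(6, 5, 4)),
                   spacing = c(0.5, 0.6, 0.7), origin = c(-3, 2, 10))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  v2 <- read_volume(f)
  expect_equal(v2$data, vol$data)
  expect_equal(v2$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, vol$origin, tolerance = 1e-5)
  expect_identical(v2$frame, "LPS")
})

test_that("RAS-affine NIfTI input is converted to the LPS frame", {
  a <- array(as.double(1:24), c(2, 3, 4))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(1, 1, 1)
  xf <- diag(4)
  xf[1:3, 4] <- c(5, 6, 7)
  img <- RNifti::`qform<-`(img, structure(xf, code = 1L))
  img <- RNifti::`sform<-`(img, structure(xf, code = 1L))
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  v <- read_volume(f)
  # +x/+y RAS directions march right/anterior: LPS requires flipped axes
  expect_equal(v$data, a[2:1, 3:1, ])
  expect_equal(v$origin, c(-6, -8, 7))
})

test_that("binary masks round-trip through NIfTI", {
  set.seed(12)
  m <- ct_mask(array(runif(4 * 4 * 4) > 0.5, c(4, 4, 4)),
               spacing = c(1, 1, 2), origin = c(0, -1, 4))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, f)
  m2 <- read_mask(f)
  expect_identical(m2$data, m$data)
  expect_equal(m2$origin, m$origin, tolerance = 1e-6)
})

test_that("DICOM series round-trip and apply the HU rescale", {
  set.seed(13)
  vol <- ct_volume(array(round(rnorm(6 * 5 * 4, 300, 200)), c(6, 5, 4)),
                   spacing = c(0.5, 0.6, 0.7), origin = c(-3, 2, 10))
  d <- withr::local_tempdir()
  write_volume(vol, d, format = "dicom_series")
  v2 <- read_volume(d)
  expect_equal(v2$data, vol$data)
  expect_equal(v2$spacing, vol$spacing, tolerance = 1e-9)
  expect_equal(v2$origin, vol$origin, tolerance = 1e-9)

  # rescale arithmetic: slope 2, intercept -1024 stores HU 500 as 762
  u <- ct_volume(array(500, c(4, 4, 2)), spacing = c(1, 1, 1))
  d2 <- withr::local_tempdir()
  write_volume(u, d2, format = "dicom_series", slope = 2, intercept = -1024)
  tags <- condylometry:::read_dicom_file(list.files(d2, full.names = TRUE)[1])
  stored <- readBin(tags[["7fe0,0010"]]$raw, "integer", n = 1, size = 2,
                    endian = "little")
  expect_identical(stored, 762L)
  expect_equal(read_volume(d2)$data[1, 1, 1], 500)
})

test_that("phantom volume written as DICOM reads back with the same mean HU", {
  ph <- generate_phantom(phantom_spec(spacing_mm = 1.2,
                                      shell_thickness_mm = 1.5, seed = 4),
                         with_mesh = FALSE)
  d <- withr::local_tempdir()
  write_volume(ph$study$volume, d, format = "dicom_series")
  v2 <- read_volume(d)
  expect_lt(abs(mean(v2$data) - mean(ph$study$volume$data)), 0.5)
})

test_that("the DICOM writer agrees with an independent reader", {
  set.seed(14)
  vol <- ct_volume(array(round(rnorm(5 * 4 * 3, 0, 400)), c(5, 4, 3)),
                   spacing = c(0.7, 0.8, 1.5), origin = c(1, 2, 3))
  d <- withr::local_tempdir()
  write_volume(vol, d, format = "dicom_series")
  script <- paste0(
    "import pydicom, glob, numpy as np\n",
    "fs = sorted(glob.glob('", d, "/*.dcm'))\n",
    "ds = [pydicom.dcmread(f) for f in fs]\n",
    "arr = np.stack([x.pixel_array * float(x.RescaleSlope) +",
    " float(x.RescaleIntercept) for x in ds])\n",
    "print(float(arr.mean()))\n")
  out <- system2("python", "-", input = script, stdout = TRUE)
  expect_equal(as.numeric(out[length(out)]), mean(vol$data),
               tolerance = 1e-8)
})

test_that("a truncated DICOM file gives a load error naming the file", {
  d <- withr::local_tempdir()
  vol <- ct_volume(array(0, c(3, 3, 2)), spacing = c(1, 1, 1))
  write_volume(vol, d, format = "dicom_series")
  f <- list.files(d, full.names = TRUE)[1]
  writeBin(readBin(f, raw(), 150), f)
  expect_error(read_volume(d), basename(f), fixed = TRUE)
})

test_that("STL meshes round-trip (welded) and PLY persists scalars", {
  cube <- mesh_from_mask(ct_mask(array(TRUE, c(1, 1, 1)),
                                 spacing = c(1, 1, 1)))
  f <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, f)
  cube2 <- read_mesh(f)
  expect_identical(nrow(cube2$faces), 12L)
  expect_identical(nrow(cube2$vertices), 8L)
  expect_equal(mesh_measures(cube2)$volume, 1)

  cube$scalars <- seq_len(8) / 10
  expect_warning(write_mesh(cube, f, format = "stl"), "scalars")
  fp <- withr::local_tempfile(fileext = ".ply")
  write_mesh(cube, fp, format = "ply")
  cube3 <- read_mesh(fp)
  expect_equal(cube3$scalars, cube$scalars)
  expect_equal(sort_rows(cube3$vertices), sort_rows(cube$vertices))
  expect_error(read_mesh(withr::local_tempfile(fileext = ".obj")),
               "file not found|unsupported")
})

test_that("landmark JSON round-trips and validates", {
  lm <- simple_landmarks()
  f <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f)
  expect_equal(lm2$points, lm$points)

  writeLines('{"condyle_apex": [0, 0, 0], "condyle_apex": [1, 1, 1]}', f)
  expect_error(read_landmarks(f), "duplicate")

  lm3 <- landmark_set(list(condyle_apex = c(0, 0, 0)))
  expect_error(ramus_height(lm3), "landmark missing: gonion_lowest")
  expect_message(landmark_set(list(condyle_apex = c(0, 0, 0),
                                   mystery_point = c(1, 2, 3))),
                 "unrecognised")
})
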