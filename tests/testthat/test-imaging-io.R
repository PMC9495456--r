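# NIfTI and DICOM round trips, the overlay contract, and the per-slice
# raw store.

test_that("NIfTI round trip preserves the voxel grid and extents", {
  ph <- generate_phantom(phantom_spec(extents = c(12, 64, 64)), seed = 2)
  d <- withr::local_tempdir()
  write_nifti_volume(ph$volume, file.path(d, "img.nii.gz"), ph$labels,
                     file.path(d, "seg.nii.gz"))
  back <- read_nifti_volume(file.path(d, "img.nii.gz"),
                            file.path(d, "seg.nii.gz"))
  expect_equal(back$volume$voxels, ph$volume$voxels, tolerance = 1e-6)
  expect_equal(back$volume$n_slices, 12L)
  expect_equal(back$volume$spacing, ph$volume$spacing, tolerance = 1e-6)
  expect_equal(back$labels$labels, ph$labels$labels)
})

test_that("mismatched image/label extents are rejected", {
  ph <- generate_phantom(phantom_spec(extents = c(6, 32, 32)), seed = 2)
  ph2 <- generate_phantom(phantom_spec(extents = c(8, 32, 32)), seed = 2)
  d <- withr::local_tempdir()
  write_nifti_volume(ph$volume, file.path(d, "img.nii.gz"))
  write_nifti_volume(ph2$volume, file.path(d, "seg.nii.gz"))
  expect_error(read_nifti_volume(file.path(d, "img.nii.gz"),
                                 file.path(d, "seg.nii.gz")), "extents")
})

test_that("label volumes validate their alphabet", {
  expect_error(label_volume(array(3, c(2, 2, 2))), "\\{0, 1, 2\\}")
})

test_that("DICOM series reading applies the modality LUT and file order", {
  d <- withr::local_tempdir()
  # three hand-built slices named so alphabetical order is c < m < z,
  # written deliberately out of order
  mk <- function(path, value, instance) {
    els <- liverseg:::ct_slice_elements(rep(value, 16), 4L, 4L, slope = 1,
                                        intercept = -1024,
                                        pixel_spacing = c(1, 1),
                                        slice_thickness = 2,
                                        series_number = 1L,
                                        instance_number = instance,
                                        sop_instance = liverseg:::dcm_uid(instance))
    liverseg:::write_dicom_file(path, els)
  }
  mk(file.path(d, "z.dcm"), 3072, 3)
  mk(file.path(d, "c.dcm"), 1024, 1)
  mk(file.path(d, "m.dcm"), 2048, 2)
  vol <- read_dicom_series(d)
  # stored 1024 with slope 1 / intercept -1024 -> 0 HU
  expect_equal(unique(as.vector(vol$voxels[1, , ])), 0)
  expect_equal(unique(as.vector(vol$voxels[2, , ])), 1024)
  expect_equal(unique(as.vector(vol$voxels[3, , ])), 2048)
  expect_equal(vol$spacing, c(2, 1, 1))
  expect_error(read_dicom_series(withr::local_tempdir()), "no DICOM")
})

test_that("a written CT series round-trips to the identical HU grid", {
  ph <- generate_phantom(phantom_spec(extents = c(5, 48, 48)), seed = 6)
  vol <- ph$volume
  vol$voxels <- round(vol$voxels)  # int16 storage is exact on integers
  d <- withr::local_tempdir()
  write_dicom_series(vol, d)
  back <- read_dicom_series(d)
  expect_equal(back$voxels, vol$voxels)
})

test_that("overlay blends per the alpha contract and sets the RGB tags", {
  ph <- generate_phantom(phantom_spec(extents = c(3, 32, 32)), seed = 4)
  vol <- ph$volume
  d0 <- withr::local_tempdir()
  zero <- array(0, dim(vol$voxels))
  write_dicom_overlay(vol, zero, zero, d0)
  f <- sort(list.files(d0, full.names = TRUE))[2]
  el <- liverseg:::read_dicom_file(f)
  expect_equal(liverseg:::dcm_string(el[["0028,0004"]]), "RGB")
  expect_equal(liverseg:::dcm_u16v(el[["0028,0002"]]), 3L)
  expect_equal(liverseg:::dcm_u16v(el[["0028,0102"]]), 7L)
  expect_equal(liverseg:::dcm_string(el[["0020,0011"]]), "2")
  # empty masks: pixel data is the windowed gray replicated to 3 channels
  g8 <- pmin(pmax(round(window_and_normalize(vol$voxels[2, , ]) * 255), 0),
             255)
  px <- as.integer(el[["7FE0,0010"]]$raw)
  rch <- matrix(px[seq(1, length(px), 3)], 32, 32, byrow = TRUE)
  gch <- matrix(px[seq(2, length(px), 3)], 32, 32, byrow = TRUE)
  expect_equal(rch, g8)
  expect_equal(gch, g8)
  # liver mask: green channel = 0.7 g + 0.3 on mask pixels, others scaled
  liver <- zero; liver[2, 10:20, 10:20] <- 1
  d1 <- withr::local_tempdir()
  write_dicom_overlay(vol, liver, zero, d1)
  el1 <- liverseg:::read_dicom_file(sort(list.files(d1, full.names = TRUE))[2])
  px1 <- as.integer(el1[["7FE0,0010"]]$raw)
  g01 <- window_and_normalize(vol$voxels[2, , ])
  want_g <- round((0.7 * g01 + 0.3) * 255)
  want_r <- round(0.7 * g01 * 255)
  gch1 <- matrix(px1[seq(2, length(px1), 3)], 32, 32, byrow = TRUE)
  rch1 <- matrix(px1[seq(1, length(px1), 3)], 32, 32, byrow = TRUE)
  expect_equal(gch1[10:20, 10:20], want_g[10:20, 10:20], tolerance = 1.01)
  expect_equal(rch1[10:20, 10:20], want_r[10:20, 10:20], tolerance = 1.01)
  # pixels outside the masks are untouched gray
  expect_equal(gch1[25:30, 25:30], g8[25:30, 25:30])
  expect_error(write_dicom_overlay(vol, zero[, 1:10, ], zero, d1),
               "extents")
})

test_that("the slice store writes one pair per slice and round-trips", {
  set.seed(91)
  imgs <- array(runif(6 * 16 * 16), c(6, 16, 16))
  msks <- array(rbinom(6 * 16 * 16, 1, 0.3), c(6, 16, 16))
  d <- withr::local_tempdir()
  n <- write_slice_store(imgs, msks, d, volume_id = "ph01")
  expect_equal(n, 6L)
  expect_length(list.files(file.path(d, "images")), 6L)
  expect_length(list.files(file.path(d, "masks")), 6L)
  st <- open_slice_store(d)
  s3 <- read_slice(st, 3)
  expect_equal(s3$image, imgs[3, , ], tolerance = 1e-6)
  expect_equal(s3$mask, msks[3, , ] + 0)
  # corrupt a file: byte-count check trips
  writeBin(numeric(10), st$image_files[2], size = 4L)
  expect_error(read_slice(st, 2), "expected")
})
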