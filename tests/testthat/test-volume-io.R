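test_that("NIfTI and NRRD round-trip voxelwise with geometry", {
  set.seed(11)
  v <- voxel_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                    spacing = c(0.3, 0.4, 0.5), origin = c(-1, 2, 3))
  for (ext in c("nii", "nii.gz", "nrrd")) {
    path <- file.path(tempdir(), paste0("roundtrip.", ext))
    save_volume(v, path)
    w <- load_volume(path)
    expect_identical(w$data, v$data, label = ext)
    expect_equal(w$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(w$origin, v$origin, tolerance = 1e-5)
    expect_identical(w$axes, "LAS")
  }
})

test_that("anisotropic NRRD spacing is preserved and masks stay binary", {
  m <- voxel_volume(array(runif(60) > 0.5, c(3, 4, 5)),
                    spacing = c(0.3, 0.4, 0.5))
  path <- file.path(tempdir(), "mask.nrrd")
  save_volume(voxel_volume(array(as.numeric(m$data), dim(m$data)),
                           spacing = m$spacing), path)
  w <- load_volume(path)
  expect_equal(w$spacing, c(0.3, 0.4, 0.5))
  expect_true(all(w$data %in% c(0, 1)))
})

test_that("corrupt or unwritable volume files raise errors", {
  bad <- file.path(tempdir(), "truncated.nii")
  writeBin(raw(100), bad)
  expect_error(load_volume(bad), "NIfTI")
  expect_error(load_volume(file.path(tempdir(), "missing.nii")), "no such file")
  v <- voxel_volume(array(0, c(2, 2, 2)))
  expect_error(save_volume(v, "/nonexistent-dir/x.nii"), "cannot write")
  expect_error(save_volume(v, file.path(tempdir(), "x.xyz")), "format")
})

test_that("DICOM series round-trips through the working frame", {
  set.seed(12)
  v <- voxel_volume(array(as.numeric(sample(-50:800, 4 * 5 * 6, TRUE)),
                          c(4, 5, 6)),
                    spacing = c(0.4, 0.4, 0.4), origin = c(1, 2, 3))
  dir <- file.path(tempdir(), "dcm-roundtrip")
  unlink(dir, recursive = TRUE)
  write_dicom_series(v, dir)
  w <- to_working_frame(load_dicom_series(dir))
  expect_identical(w$data, v$data)
  expect_equal(w$spacing, v$spacing, tolerance = 1e-9)
  expect_equal(w$origin, v$origin, tolerance = 1e-6)
})

test_that("DICOM reader rejects invalid series", {
  v <- voxel_volume(array(0:63, c(4, 4, 4)), spacing = c(0.4, 0.4, 0.4))
  one <- file.path(tempdir(), "dcm-single")
  unlink(one, recursive = TRUE)
  paths <- write_dicom_series(v, one)
  file.remove(paths[-1])
  expect_error(load_dicom_series(one), ">= 2")
  mixed <- file.path(tempdir(), "dcm-mixed")
  unlink(mixed, recursive = TRUE)
  write_dicom_series(v, mixed, series_uid = "1.2.3.1")
  v2 <- v; v2$origin <- v$origin + c(0, 0, 10)
  write_dicom_series(v2, file.path(tempdir(), "dcm-mixed2"),
                     series_uid = "1.2.3.2")
  file.copy(list.files(file.path(tempdir(), "dcm-mixed2"), full.names = TRUE)[1],
            file.path(mixed, "other.dcm"))
  expect_error(load_dicom_series(mixed), "SeriesInstanceUID")
})

test_that("to_working_frame permutes, flips and is idempotent", {
  set.seed(13)
  arr <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  las <- voxel_volume(arr, spacing = c(0.3, 0.4, 0.5), origin = c(-1, 2, 3))
  # same volume expressed with axes (anterior, right, superior)
  ars <- voxel_volume(aperm(arr, c(2, 1, 3))[, 4:1, , drop = FALSE],
                      spacing = c(0.4, 0.3, 0.5),
                      origin = c(-1 + 3 * 0.3, 2, 3), axes = "ARS")
  wf <- to_working_frame(ars)
  expect_identical(wf$data, arr)
  expect_equal(wf$origin, las$origin)
  expect_equal(wf$spacing, las$spacing)
  expect_identical(to_working_frame(wf), wf)
  # unknown orientation needs an override
  unk <- las; unk$axes <- NA
  expect_error(to_working_frame(unk), "assume")
  expect_identical(to_working_frame(unk, assume = "LAS")$data, arr)
})

test_that("y-flip moves the phantom apex to the +y side", {
  ph <- coarse_phantom()
  v <- ph$volume
  dims <- dim(v$data)
  flipped <- voxel_volume(v$data[, dims[2]:1, , drop = FALSE],
                          spacing = v$spacing,
                          origin = c(v$origin[1],
                                     v$origin[2] + (dims[2] - 1) * v$spacing[2],
                                     v$origin[3]),
                          axes = "LPS")
  wf <- to_working_frame(flipped)
  mask <- wf$data > 700
  pts <- which(mask, arr.ind = TRUE)
  mm_y <- wf$origin[2] + (pts[, 2] - 1) * wf$spacing[2]
  # apex stays the anterior (+y) extreme after mapping
  expect_gt(max(mm_y), 0.95 * ph$truth$apex_mm[2])
})
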