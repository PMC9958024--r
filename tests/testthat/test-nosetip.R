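test_that("render_frontal projects columns and counts occupied pixels", {
  arr <- array(FALSE, c(8, 6, 7))
  arr[3, 4, 5] <- TRUE
  m <- voxel_volume(arr, spacing = c(1, 1, 1))
  pr <- render_frontal(m)
  expect_identical(sum(pr$image), 1L)
  expect_true(pr$image[3, 5])
  # solid box -> filled rectangle of the box's x-z extent
  arr2 <- array(FALSE, c(10, 10, 10))
  arr2[3:7, 2:4, 5:9] <- TRUE
  pr2 <- render_frontal(voxel_volume(arr2, spacing = c(1, 1, 1)))
  expect_identical(sum(pr2$image), 25L)
  expect_true(all(pr2$image[3:7, 5:9]))
  # phantom silhouette area equals the occupied-column count
  mask <- coarse_mask()
  pr3 <- render_frontal(mask)
  expect_identical(sum(pr3$image),
                   sum(apply(mask$data, c(1, 3), any)))
})

test_that("auto_nose_roi applies the stated silhouette fractions", {
  # silhouette spanning x in [0,100], z in [0,200] mm
  img <- matrix(FALSE, 101, 201)
  img[, 1] <- TRUE; img[, 201] <- TRUE; img[1, ] <- TRUE; img[101, ] <- TRUE
  pr <- structure(list(image = img, x_mm = 0:100, z_mm = 0:200),
                  class = "frontal_projection")
  roi <- auto_nose_roi(pr)
  expect_equal(roi$x_range, c(35, 65))
  expect_equal(roi$z_range, c(60, 120))
  tiny <- structure(list(image = matrix(TRUE, 5, 5), x_mm = 1:5, z_mm = 1:5),
                    class = "frontal_projection")
  expect_error(auto_nose_roi(tiny), "too small")
})

test_that("detect_nose_tip finds a pyramidal spike apex exactly", {
  arr <- array(FALSE, c(30, 30, 30))
  arr[8:22, 5:15, 8:22] <- TRUE             # cube
  for (k in 0:4) arr[15 + (-k:k), 20 - k, 15 + (-k:k)] <- TRUE # apex at +y
  m <- voxel_volume(arr, spacing = c(1, 1, 1))
  m <- cbctreorient:::as_skull_mask(m$data, m)
  roi <- cbctreorient:::nose_roi(c(11, 17), c(11, 17))
  tip <- detect_nose_tip(m, roi, apex_band_mm = 0.5)
  expect_lt(sqrt(sum((tip$position - c(14, 19, 14))^2)), 0.51)
  expect_identical(tip$support_count, 1L)
})

test_that("detect_nose_tip on a sphere averages the anterior cap", {
  arr <- array(FALSE, c(41, 41, 41))
  idx <- which(arr == FALSE, arr.ind = TRUE)
  r2 <- (idx[, 1] - 21)^2 + (idx[, 2] - 21)^2 + (idx[, 3] - 21)^2
  arr[r2 <= 15^2] <- TRUE
  m <- voxel_volume(arr, spacing = c(1, 1, 1))
  m <- cbctreorient:::as_skull_mask(m$data, m)
  roi <- cbctreorient:::nose_roi(c(16, 24), c(16, 24))
  tip <- detect_nose_tip(m, roi, apex_band_mm = 2)
  pole <- c(20, 20 + 15, 20)  # anterior pole in mm (0-based grid)
  expect_lt(sqrt(sum((tip$position - pole)^2)), 2)
})

test_that("detect_nose_tip recovers the phantom apex within its geometric bound", {
  # the averaged anterior band sits up to apex_band behind the apex, and the
  # voxel lattice adds about half a voxel of quantization
  ph <- coarse_phantom()
  tip <- detect_nose_tip(coarse_mask())
  err <- sqrt(sum((tip$position - ph$truth$apex_mm)^2))
  expect_lt(err, 2 + ph$volume$spacing[1] / 2)
  expect_gte(tip$support_count, 1)
})

test_that("detect_nose_tip is translation equivariant", {
  mask <- coarse_mask()
  tip <- detect_nose_tip(mask)
  shift <- c(7.5, -3, 12)
  moved <- mask
  moved$origin <- mask$origin + shift
  tip2 <- detect_nose_tip(moved)
  expect_equal(tip2$position, tip$position + shift, tolerance = 1e-9)
})

test_that("detected tip lies on the convex hull, not interior", {
  mask <- coarse_mask()
  tip <- detect_nose_tip(mask)
  surf <- cbctreorient:::surface_mask(mask$data)
  pts <- cbctreorient:::mask_points_mm(surf, mask$spacing, mask$origin)
  hv <- pts[convex_hull_vertices(pts), , drop = FALSE]
  d <- sqrt(min(rowSums(sweep(hv, 2, tip$position)^2)))
  expect_lte(d, sqrt(sum(mask$spacing^2)))
})

test_that("empty ROI raises a detection error", {
  mask <- coarse_mask()
  far <- cbctorient_far_roi <- cbctreorient:::nose_roi(c(-200, -150), c(-200, -150))
  expect_error(detect_nose_tip(mask, far), "ROI")
})
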