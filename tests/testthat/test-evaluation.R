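test_that("hausdorff matches hand values and the brute-force oracle", {
  expect_equal(hausdorff(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1)), 5)
  A <- matrix(c(1, 2, 3, 4, 5, 6), 2, byrow = TRUE)
  expect_equal(hausdorff(A, A), 0)
  A2 <- rbind(c(0, 0, 0), c(10, 0, 0))
  B2 <- matrix(c(0, 1, 0), 1)
  expect_equal(hausdorff(A2, B2), oracle_hausdorff(A2, B2))
  expect_error(hausdorff(A2, matrix(numeric(0), ncol = 3)), "empty")
})

test_that("hausdorff is symmetric, nonnegative and rigid invariant", {
  set.seed(41)
  for (i in 1:10) {
    A <- matrix(rnorm(3 * sample(5:60, 1), sd = 10), ncol = 3)
    B <- matrix(rnorm(3 * sample(5:60, 1), sd = 10), ncol = 3)
    h <- hausdorff(A, B)
    expect_gte(h, 0)
    expect_equal(h, hausdorff(B, A))
    expect_equal(h, oracle_hausdorff(A, B), tolerance = 1e-12)
    tf <- rigid_transform(rotation_from_angles(runif(3, -180, 180)),
                          runif(3, -20, 20))
    expect_equal(hausdorff(apply_rigid(tf, A), apply_rigid(tf, B)), h,
                 tolerance = 1e-9)
  }
})

test_that("matching_improvement follows its definition", {
  expect_equal(matching_improvement(10, 5), 50)
  expect_equal(matching_improvement(8, 8), 0)
  expect_equal(matching_improvement(4, 6), -50)
  expect_error(matching_improvement(0, 1), "undefined")
})

test_that("extract_forehead counts anterior band voxels of a box exactly", {
  arr <- array(FALSE, c(30, 20, 60))
  arr[6:25, 5:10, 6:55] <- TRUE  # solid box, anterior face at y index 10
  v <- voxel_volume(arr, spacing = c(1, 1, 1))
  mask <- cbctreorient:::as_skull_mask(arr, v)
  tip <- structure(list(position = c(15, 9, 10), support_count = 1),
                   class = "nose_tip")
  pts <- extract_forehead(mask, tip, z_lo = 20, z_hi = 40)
  # anterior face: 20 x-columns, z in [30, 50] -> 21 rows
  expect_identical(nrow(pts), 20L * 21L)
  expect_true(all(pts[, 2] == 9))
  # brute-force boundary + box filter on the phantom
  ph_mask <- coarse_mask()
  ph_tip <- detect_nose_tip(ph_mask)
  fh <- extract_forehead(ph_mask, ph_tip)
  d <- ph_mask$data
  dims <- dim(d)
  shifted <- array(FALSE, dims)
  shifted[, 1:(dims[2] - 1), ] <- d[, 2:dims[2], ]
  ant <- d & !shifted
  pts2 <- cbctreorient:::mask_points_mm(ant, ph_mask$spacing, ph_mask$origin)
  keep <- pts2[, 3] >= ph_tip$position[3] + 20 &
    pts2[, 3] <= ph_tip$position[3] + 70 &
    pts2[, 2] >= ph_tip$position[2] - 80
  pts2 <- pts2[keep, , drop = FALSE]
  # exterior front surface: most anterior voxel per (x, z) column
  o <- order(pts2[, 1], pts2[, 3], -pts2[, 2])
  pts2 <- pts2[o, , drop = FALSE]
  pts2 <- pts2[!duplicated(pts2[, c(1, 3), drop = FALSE]), , drop = FALSE]
  expect_identical(nrow(fh), nrow(pts2))
  expect_equal(fh[order(fh[, 1], fh[, 3]), ], pts2[order(pts2[, 1], pts2[, 3]), ],
               ignore_attr = TRUE)
  # tip above the vertex -> empty band
  high <- structure(list(position = c(0, 120, 500), support_count = 1),
                    class = "nose_tip")
  expect_error(extract_forehead(ph_mask, high), "forehead")
})

test_that("evaluate_serial reports identity alignment as 100% improvement", {
  arr <- array(FALSE, c(20, 12, 40))
  arr[5:15, 4:8, 5:35] <- TRUE
  v <- voxel_volume(arr, spacing = c(1, 1, 1))
  mask <- cbctreorient:::as_skull_mask(arr, v)
  tip <- structure(list(position = c(10, 7, 6), support_count = 1),
                   class = "nose_tip")
  # before: translated copies in raw mode; after: identical masks
  m2 <- mask; m2$origin <- mask$origin + c(0, 3, 0)
  m3 <- mask; m3$origin <- mask$origin + c(0, -2, 0)
  rep <- evaluate_serial(list(mask, m2, m3), list(mask, mask, mask),
                         list(tip, tip, tip), z_lo = 5, z_hi = 25,
                         before_arranged = FALSE)
  expect_identical(rep$pair, c("T0T1", "T0T2", "T1T2"))
  expect_true(all(rep$hd_after == 0))
  expect_true(all(rep$hd_before > 0))
  expect_true(all(rep$improvement_pct == 100))
  # mismatched lattices are rejected
  bad <- cbctreorient:::as_skull_mask(arr[, , 1:39],
                                      voxel_volume(arr[, , 1:39]))
  expect_error(evaluate_serial(list(mask, m2), list(mask, bad),
                               list(tip, tip), 5, 25), "lattice")
})
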