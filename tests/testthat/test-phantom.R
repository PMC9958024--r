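test_that("phantom construction is deterministic with noise isolated", {
  spec <- phantom_spec(spacing = 2, seed = 5)
  ph1 <- phantom_generate(spec)
  ph2 <- phantom_generate(spec)
  expect_identical(ph1$volume$data, ph2$volume$data)
  spec2 <- phantom_spec(spacing = 2, seed = 6)
  ph3 <- phantom_generate(spec2)
  expect_identical(ph1$truth$bone_mask$data, ph3$truth$bone_mask$data)
  expect_false(identical(ph1$volume$data, ph3$volume$data))
  expect_identical(ph1$truth$clean, ph3$truth$clean)
})

test_that("the analytic apex is the anterior extreme of the bone", {
  ph <- coarse_phantom(noise = FALSE)
  apex <- ph$truth$apex_mm
  spec <- phantom_spec()
  a <- spec$semi_axes
  expect_equal(apex,
               c(0, a[2] * sqrt(1 - (spec$nose_apex_z / a[3])^2) +
                   spec$nose_length, spec$nose_apex_z))
  pts <- cbctreorient:::mask_points_mm(ph$truth$bone_mask$data,
                                       ph$volume$spacing,
                                       ph$volume$origin)
  expect_lt(max(pts[, 2]), apex[2] + 1e-9)
  expect_gt(max(pts[, 2]), apex[2] - 2 * ph$volume$spacing[2])
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(nose_length = 5, shell_thickness = 6), "invalid")
  expect_error(phantom_spec(menton_deviation = -1))
  expect_error(generate_cohort(9, list(c(4, 4.5), c(5, 4), c(9, 12))),
               "band")
  expect_error(generate_cohort(2), "n >= 3")
})

test_that("menton deviation displaces the wedge tip laterally", {
  for (dev in c(0, 12)) {
    ph <- phantom_generate(phantom_spec(spacing = 2, menton_deviation = dev,
                                        noise_sd = 0))
    bone <- ph$truth$bone_mask$data
    pts <- cbctreorient:::mask_points_mm(bone, ph$volume$spacing,
                                         ph$volume$origin)
    # the wedge tip region: at the menton height, anterior of the shell ring
    ztip <- -(phantom_spec()$semi_axes[3] - 5)
    low <- pts[abs(pts[, 3] - ztip) <= 1 & pts[, 2] > 35, , drop = FALSE]
    expect_gt(nrow(low), 0)
    expect_equal(mean(low[, 1]), dev, tolerance = 0.5, ignore_attr = TRUE,
                 label = sprintf("deviation %g centroid", dev))
    expect_equal(ph$truth$menton_deviation, dev)
  }
})

test_that("perturbation transforms the truth analytically", {
  ph <- coarse_phantom()
  same <- phantom_perturb(ph$volume, ph$truth, c(0, 0, 0), c(0, 0, 0),
                          seed = 9)
  expect_equal(same$truth$apex_mm, ph$truth$apex_mm)
  ang <- c(0, 0, 10); tr <- c(4, -3, 2)
  pp <- phantom_perturb(ph$volume, ph$truth, ang, tr, seed = 9)
  dims <- dim(ph$volume$data)
  center <- ph$volume$origin + (dims - 1) / 2 * ph$volume$spacing
  R <- rotation_from_angles(ang)
  expect_equal(pp$truth$apex_mm,
               as.numeric(R %*% (ph$truth$apex_mm - center)) + center + tr)
  expect_equal(pp$truth$applied_transform$rotation, R)
  # perturbation limits enforced
  expect_error(phantom_perturb(ph$volume, ph$truth, c(25, 0, 0), c(0, 0, 0)))
})

test_that("sequential perturbations accumulate applied_transform correctly", {
  ph <- coarse_phantom()
  p1 <- phantom_perturb(ph$volume, ph$truth, c(3, -4, 6), c(2, 1, -3), seed = 1)
  p2 <- phantom_perturb(p1$volume, p1$truth, c(-5, 2, 1), c(0, -2, 4), seed = 2)
  # the accumulated transform maps the pristine apex onto the current apex
  expect_equal(apply_rigid(p1$truth$applied_transform, ph$truth$apex_mm),
               p1$truth$apex_mm, tolerance = 1e-9)
  expect_equal(apply_rigid(p2$truth$applied_transform, ph$truth$apex_mm),
               p2$truth$apex_mm, tolerance = 1e-9)
  # pairwise relative transform of the recorded poses
  T1 <- p1$truth$applied_transform
  t0 <- T1$translation + T1$center - as.numeric(T1$rotation %*% T1$center)
  inv1 <- rigid_transform(t(T1$rotation),
                          -as.numeric(t(T1$rotation) %*% t0))
  rel <- compose_rigid(p2$truth$applied_transform, inv1)
  expect_equal(apply_rigid(rel, p1$truth$apex_mm), p2$truth$apex_mm,
               tolerance = 1e-9)
})
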