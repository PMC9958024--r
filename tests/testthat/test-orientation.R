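make_mask <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- voxel_volume(arr, spacing = spacing, origin = origin)
  cbctreorient:::as_skull_mask(v$data, v)
}

test_that("extract_sphere_roi matches the analytic ball volume and brute force", {
  arr <- array(FALSE, c(101, 101, 101))
  idx <- which(!arr, arr.ind = TRUE)
  r2 <- (idx[, 1] - 51)^2 + (idx[, 2] - 51)^2 + (idx[, 3] - 51)^2
  arr[r2 <= 50^2] <- TRUE
  mask <- make_mask(arr)
  tip <- structure(list(position = c(50, 50, 50), support_count = 1),
                   class = "nose_tip")
  roi <- extract_sphere_roi(mask, tip, radius = 35)
  expect_equal(nrow(roi$points), 4 / 3 * pi * 35^3, tolerance = 0.02)
  # brute-force distance filter over all mask voxels
  pts <- cbctreorient:::mask_points_mm(arr, c(1, 1, 1), c(0, 0, 0))
  d2 <- rowSums(sweep(pts, 2, tip$position)^2)
  expect_identical(nrow(roi$points), sum(d2 <= 35^2))
  # tip far outside the mask support
  tip2 <- structure(list(position = c(5, 5, 5), support_count = 1),
                    class = "nose_tip")
  expect_error(extract_sphere_roi(mask, tip2, radius = 10), "degenerate")
})

test_that("pca_axes matches closed-form uniform-box variances", {
  set.seed(31)
  g <- as.matrix(expand.grid(x = seq(0.5, 39.5, 1), y = seq(0.5, 9.5, 1),
                             z = seq(0.5, 29.5, 1)))
  roi <- structure(list(points = g, radius = Inf, center = colMeans(g)),
                   class = "sphere_roi")
  p <- pca_axes(roi)
  expect_equal(p$values, c(40^2, 30^2, 10^2) / 12, tolerance = 0.05)
  expect_gt(abs(p$vectors[1, 1]), 0.999)  # largest variance along x
  expect_gt(abs(p$vectors[3, 2]), 0.999)  # then z
  expect_gt(abs(p$vectors[2, 3]), 0.999)  # smallest along y
  # spectral identity on a random cloud
  pts <- matrix(rnorm(300), ncol = 3) %*% diag(c(3, 2, 1))
  pr <- pca_axes(pts)
  covm <- stats::cov(pts)
  expect_equal(pr$vectors %*% diag(pr$values) %*% t(pr$vectors), covm,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("flat plates give exact anteroposterior axes and degeneracy errors", {
  g <- as.matrix(expand.grid(x = 1:20, y = 0, z = 1:20))
  roi <- structure(list(points = g, radius = Inf, center = c(10.5, 8, 10.5)),
                   class = "sphere_roi")
  p <- pca_axes(roi)
  expect_equal(p$values[3], 0)
  expect_equal(abs(p$vectors[, 3]), c(0, 1, 0))
  # tip on the +y side forces y = (0, 1, 0) exactly
  expect_equal(determine_y_axis(roi), c(0, 1, 0))
  # collinear points have rank-1 covariance
  line <- cbind(1:50, 2 * (1:50), 3 * (1:50))
  expect_error(pca_axes(line), "rank")
})

test_that("project_binarize rasterizes a ball ROI into the analytic disk", {
  arr <- array(FALSE, c(101, 101, 101))
  idx <- which(!arr, arr.ind = TRUE)
  r2 <- (idx[, 1] - 51)^2 + (idx[, 2] - 51)^2 + (idx[, 3] - 51)^2
  arr[r2 <= 40^2] <- TRUE
  mask <- make_mask(arr)
  tip <- structure(list(position = c(50, 50, 50), support_count = 1),
                   class = "nose_tip")
  roi <- extract_sphere_roi(mask, tip, radius = 35)
  pr <- project_binarize(roi, c(0, 1, 0), pixel_mm = 1)
  expect_equal(sum(pr$image), pi * 35^2, tolerance = 0.03)
  # single point -> single on-pixel
  one <- structure(list(points = matrix(c(3, 4, 5), 1), radius = 1,
                        center = c(3, 4, 5)), class = "sphere_roi")
  pr1 <- project_binarize(one, c(0, 1, 0))
  expect_identical(sum(pr1$image), 1L)
})

test_that("determine_x_axis is exact on a symmetric disk and errors when degenerate", {
  th <- seq(0, 2 * pi, length.out = 720)
  disk <- do.call(rbind, lapply(seq(0, 20, 0.5), function(r) {
    cbind(r * cos(th), 0, r * sin(th))
  }))
  roi <- structure(list(points = disk, radius = 21, center = c(0, 5, 0)),
                   class = "sphere_roi")
  pr <- project_binarize(roi, c(0, 1, 0), pixel_mm = 1)
  x <- determine_x_axis(pr)
  expect_equal(x, c(1, 0, 0), tolerance = 1e-6)
  # single on-pixel in the bottom half
  lone <- structure(list(points = matrix(c(0, 0, -3), 1), radius = 5,
                         center = c(0, 0, 0)), class = "sphere_roi")
  expect_error(determine_x_axis(project_binarize(lone, c(0, 1, 0))),
               "degenerate|inferior half")
})

test_that("complete_axes builds exact right-handed frames", {
  ax <- complete_axes(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(ax$z_axis, c(0, 0, 1))
  # 1 degree of non-orthogonality is absorbed by Gram-Schmidt
  y <- c(0, 1, 0)
  x <- c(cos(pi / 180) * 1, sin(pi / 180), 0)
  ax2 <- complete_axes(x, y, c(1, 2, 3))
  R <- rbind(ax2$x_axis, ax2$y_axis, ax2$z_axis)
  expect_equal(R %*% t(R), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(R), 1, tolerance = 1e-9)
  expect_lt(angle_deg(ax2$x_axis, x), 1.01)
  expect_equal(ax2$origin, c(1, 2, 3))
  # gross non-orthogonality is an upstream inconsistency
  expect_error(complete_axes(c(0, 0.99, 0.14), c(0, 1, 0), c(0, 0, 0)),
               "inconsistent")
})

test_that("rotation_angle reproduces axis-angle values", {
  expect_equal(rotation_angle(diag(3)), 0)
  expect_equal(rotation_angle(rotation_from_angles(c(0, 0, 90))), 90)
  R <- rotation_from_angles(c(5, 0, 0)) %*% rotation_from_angles(c(0, 5, 0))
  expected <- acos((sum(diag(R)) - 1) / 2) * 180 / pi
  expect_equal(rotation_angle(R), expected)
  ax <- complete_axes(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(rotation_angle(ax), 0)
})

test_that("reorient_volume with identity axes is the identity and masks stay binary", {
  ph <- coarse_phantom()
  v <- ph$volume
  ax <- complete_axes(c(1, 0, 0), c(0, 1, 0), c(10, 120, -12))
  out <- reorient_volume(v, ax)
  expect_equal(out$data, v$data, tolerance = 1e-12)
  mask <- coarse_mask()
  ax2 <- complete_axes(c(cos(0.2), 0, -sin(0.2)), c(0, 1, 0), c(0, 120, -12))
  rmask <- reorient_volume(mask, ax2, interpolation = "nearest")
  expect_true(is.logical(rmask$data))
})

test_that("reorienting a rotated phantom reproduces the unrotated reorientation", {
  ph <- coarse_phantom()
  base <- process_volume(ph$volume)
  pp <- phantom_perturb(ph$volume, ph$truth, c(6, -8, 5), c(4, -6, 3), seed = 5)
  rot <- process_volume(pp$volume)
  shift_dice <- function(B, A, tipB, tipA) {
    # arrange the two reoriented grids on their tips, nearest resample
    off <- (tipB - tipA) / ph$volume$spacing
    Bd <- B; storage.mode(Bd) <- "double"
    Bs <- cbctreorient:::.resample_affine(Bd, dim(B), dim(A), diag(3), off,
                                          FALSE, 0) > 0.5
    2 * sum(A & Bs) / (sum(A) + sum(Bs))
  }
  dice_after <- shift_dice(rot$reoriented_mask$data, base$reoriented_mask$data,
                           rot$tip$position, base$tip$position)
  dice_before <- shift_dice(rot$mask$data, base$mask$data,
                            rot$tip$position, base$tip$position)
  # a 6 mm shell with ~1 mm residual misalignment cannot reach Dice ~1, but
  # reorientation must restore most of the overlap the rotation destroyed
  expect_gte(dice_after, 0.8)
  expect_gt(dice_after, dice_before + 0.2)
})

test_that("estimated frames are orthonormal and commute with arrangement", {
  mask <- coarse_mask()
  tip <- detect_nose_tip(mask)
  ax <- estimate_axes(mask, tip)
  R <- rbind(ax$x_axis, ax$y_axis, ax$z_axis)
  expect_equal(R %*% t(R), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(R), 1, tolerance = 1e-9)
  # translating the volume first (arrangement) must not change the axes
  moved <- mask
  moved$origin <- mask$origin - tip$position
  tip2 <- detect_nose_tip(moved)
  ax2 <- estimate_axes(moved, tip2)
  expect_equal(ax2$x_axis, ax$x_axis, tolerance = 1e-6)
  expect_equal(ax2$y_axis, ax$y_axis, tolerance = 1e-6)
  expect_equal(ax2$z_axis, ax$z_axis, tolerance = 1e-6)
  expect_equal(ax2$origin, ax$origin - tip$position, tolerance = 1e-6)
})
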