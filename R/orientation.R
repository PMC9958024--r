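# Core method: estimate an individualized orthonormal head frame from the
# bone voxels inside a sphere around the nose tip.

#' Extract the spherical ROI around the nose tip
#'
#' All mask voxel centres within `radius` mm of the tip, as mm coordinates.
#' The default radius of 35 mm captures the nasal pyramid and the
#' naso-orbital bone shell whose thin, face-parallel distribution drives the
#' PCA: variance is large along the face and small through its depth.
#'
#' @param mask a `skull_mask`.
#' @param tip a `nose_tip` (or length-3 mm position).
#' @param radius sphere radius in mm (default 35).
#' @return A `sphere_roi`: list with `points` (N x 3 mm), `radius`, `center`.
#' @export
extract_sphere_roi <- function(mask, tip, radius = 35) {
  stopifnot(is_voxel_volume(mask), radius > 0)
  center <- tip_position(tip)
  dims <- dim(mask$data)
  # crop to the bounding window of the sphere before the distance filter
  lo <- pmax(1, floor((center - radius - mask$origin) / mask$spacing) + 1)
  hi <- pmin(dims, ceiling((center + radius - mask$origin) / mask$spacing) + 1)
  if (any(lo > hi)) stop("sphere ROI does not intersect the mask grid",
                         call. = FALSE)
  sub <- mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_origin <- mask$origin + (lo - 1) * mask$spacing
  pts <- mask_points_mm(sub, mask$spacing, sub_origin)
  if (nrow(pts) > 0) {
    d2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
      (pts[, 3] - center[3])^2
    pts <- pts[d2 <= radius^2, , drop = FALSE]
  }
  if (nrow(pts) < 100) {
    stop(sprintf("degenerate sphere ROI: only %d mask voxels within %g mm",
                 nrow(pts), radius), call. = FALSE)
  }
  structure(list(points = pts, radius = radius, center = center),
            class = "sphere_roi")
}

tip_position <- function(tip) {
  if (inherits(tip, "nose_tip")) tip$position else as.numeric(tip)
}

roi_points <- function(points) {
  if (inherits(points, "sphere_roi")) points$points else as.matrix(points)
}

#' Principal axes of an ROI point cloud
#'
#' Eigen-decomposition of the 3x3 covariance of the centred points.
#'
#' @param points a `sphere_roi` or N x 3 matrix.
#' @return List with `values` (variances, descending), `vectors` (unit
#'   eigenvectors as columns, matching order) and `centroid`.
#' @export
pca_axes <- function(points) {
  pts <- roi_points(points)
  if (nrow(pts) < 3) stop("too few points for PCA", call. = FALSE)
  centroid <- colMeans(pts)
  centered <- sweep(pts, 2, centroid)
  covm <- crossprod(centered) / (nrow(pts) - 1)
  eig <- eigen(covm, symmetric = TRUE)
  if (eig$values[2] <= max(eig$values[1], 1) * 1e-12) {
    stop("degenerate point cloud: covariance rank < 2", call. = FALSE)
  }
  list(values = eig$values, vectors = eig$vectors, centroid = centroid)
}

#' Anteroposterior (y) axis from the spherical ROI
#'
#' The new y axis is the eigenvector of the smallest PCA component: within
#' the sphere the bone is a thin curved plate, thinnest through the depth of
#' the face. The eigenvector sign is chosen so that y points from the ROI
#' centroid towards the sphere centre (the nose tip), i.e. anteriorly out of
#' the face. A relative gap below 1% between the two smallest eigenvalues
#' triggers a warning (near-isotropic ROI) but the deterministic eigenvector
#' order is still used.
#'
#' @param points a `sphere_roi`.
#' @return Unit length-3 vector.
#' @export
determine_y_axis <- function(points) {
  stopifnot(inherits(points, "sphere_roi"))
  pca <- pca_axes(points)
  lam <- pca$values
  if (lam[2] > 0 && (lam[2] - lam[3]) / lam[2] < 0.01) {
    warning("smallest two PCA components within 1%: anteroposterior axis may be ambiguous")
  }
  y <- pca$vectors[, 3]
  outward <- points$center - pca$centroid
  if (sum(y * outward) < 0) y <- -y
  y / sqrt(sum(y^2))
}

#' Binarized projection of the ROI along the y axis
#'
#' Projects the ROI points onto the plane orthogonal to `y_axis` and
#' rasterizes them at `pixel_mm`; a pixel is on iff at least one point
#' projects into it. The in-plane basis is `u` (working x minus its y
#' component, normalized) and `w = y x u`.
#'
#' @param points a `sphere_roi`.
#' @param y_axis unit length-3 vector.
#' @param pixel_mm raster pixel size in mm (default 1).
#' @return A `roi_projection`: list with `image` (logical matrix, u along
#'   rows), `u`, `w`, `u0`, `w0` (mm coordinates of pixel `[1,1]` centre)
#'   and `pixel_mm`. Projections are relative to the sphere centre.
#' @export
project_binarize <- function(points, y_axis, pixel_mm = 1) {
  stopifnot(inherits(points, "sphere_roi"), pixel_mm > 0)
  y <- y_axis / sqrt(sum(y_axis^2))
  ex <- c(1, 0, 0)
  u <- ex - sum(ex * y) * y
  if (sqrt(sum(u^2)) < 1e-6) {
    # y is (anti)parallel to working x; fall back to working z for the basis
    u <- c(0, 0, 1) - sum(c(0, 0, 1) * y) * y
  }
  u <- u / sqrt(sum(u^2))
  w <- c(y[2] * u[3] - y[3] * u[2],
         y[3] * u[1] - y[1] * u[3],
         y[1] * u[2] - y[2] * u[1])
  rel <- sweep(points$points, 2, points$center)
  a <- rel %*% u
  b <- rel %*% w
  ia <- floor((a - min(a)) / pixel_mm)
  ib <- floor((b - min(b)) / pixel_mm)
  na <- max(ia) + 1L
  nb <- max(ib) + 1L
  img <- matrix(FALSE, na, nb)
  img[cbind(ia + 1, ib + 1)] <- TRUE
  structure(
    list(image = img, u = u, w = w,
         u0 = min(a) + pixel_mm / 2, w0 = min(b) + pixel_mm / 2,
         pixel_mm = pixel_mm),
    class = "roi_projection"
  )
}

#' Transverse (x) axis from the projected ROI
#'
#' Restricted to the inferior half of the projection (pixels whose
#' superoinferior coordinate lies below the image centre), the two far ends
#' of the transverse extent are selected; the straight line through them is
#' the new x axis. The extreme column of a rasterized smooth silhouette is
#' attained by a run of pixels (a flat raster edge), so each far end is
#' taken as the mean position of the pixels attaining the extreme — a
#' sub-pixel estimate of the tangency point that is stable against raster
#' phase. The sign is chosen so that the axis points towards working
#' patient-left (+x).
#'
#' @param projection a `roi_projection` from [project_binarize()].
#' @return Unit length-3 vector.
#' @export
determine_x_axis <- function(projection) {
  stopifnot(inherits(projection, "roi_projection"))
  img <- projection$image
  on <- which(img, arr.ind = TRUE)
  if (nrow(on) == 0) stop("empty projection", call. = FALSE)
  px <- projection$pixel_mm
  a <- projection$u0 + (on[, 1] - 1) * px
  b <- projection$w0 + (on[, 2] - 1) * px
  # inferior measure: projection of the pixel centre onto working -z
  ez_u <- projection$u[3]
  ez_w <- projection$w[3]
  zc <- a * ez_u + b * ez_w
  bottom <- zc < (min(zc) + max(zc)) / 2
  if (!any(bottom)) stop("inferior half of the projection is empty",
                         call. = FALSE)
  ab <- cbind(a, b)[bottom, , drop = FALSE]
  pick <- function(side) {
    extreme <- if (side > 0) max(ab[, 1]) else min(ab[, 1])
    cand <- which(ab[, 1] == extreme)
    c(extreme, mean(ab[cand, 2]))  # centre of the flat raster edge
  }
  pL <- pick(-1)
  pR <- pick(+1)
  if (all(pL == pR)) stop("degenerate projection: single transverse extreme",
                          call. = FALSE)
  d_ab <- pR - pL
  x <- d_ab[1] * projection$u + d_ab[2] * projection$w
  n <- sqrt(sum(x^2))
  if (n == 0) stop("degenerate projection: coincident extremes", call. = FALSE)
  x <- x / n
  if (x[1] < 0) x <- -x
  x
}

#' Complete the global axes
#'
#' Given the PCA-derived y axis and the projection-derived x axis, derives
#' the superoinferior z axis as `x cross y` (re-signed towards working
#' superior) and re-orthogonalizes: y is kept exactly (it is the most
#' data-driven axis), x is recomputed as `y cross z`. Inputs more than
#' `acos(0.05)` away from orthogonal signal an upstream inconsistency.
#'
#' @param x,y unit length-3 vectors.
#' @param tip `nose_tip` or length-3 mm position; becomes the frame origin.
#' @param eigenvalues optional length-3 PCA variances stored with the frame.
#' @return A `global_axes`: list with unit `x_axis`, `y_axis`, `z_axis`,
#'   `origin` and `eigenvalues`.
#' @export
complete_axes <- function(x, y, tip, eigenvalues = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  y <- y / sqrt(sum(y^2))
  if (abs(sum(x * y)) >= 0.05) {
    stop("x and y axes are inconsistent (|x.y| >= 0.05)", call. = FALSE)
  }
  x <- x - sum(x * y) * y
  x <- x / sqrt(sum(x^2))
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  if (z[3] < 0) z <- -z
  z <- z / sqrt(sum(z^2))
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  structure(
    list(x_axis = x, y_axis = y, z_axis = z,
         origin = tip_position(tip),
         eigenvalues = if (is.null(eigenvalues)) rep(NA_real_, 3)
                       else as.numeric(eigenvalues)),
    class = "global_axes"
  )
}

#' @export
print.global_axes <- function(x, ...) {
  cat("<global_axes>\n")
  cat(sprintf("  x: (% .4f, % .4f, % .4f)\n", x$x_axis[1], x$x_axis[2], x$x_axis[3]))
  cat(sprintf("  y: (% .4f, % .4f, % .4f)\n", x$y_axis[1], x$y_axis[2], x$y_axis[3]))
  cat(sprintf("  z: (% .4f, % .4f, % .4f)\n", x$z_axis[1], x$z_axis[2], x$z_axis[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, rotation %.2f deg\n",
              x$origin[1], x$origin[2], x$origin[3], rotation_angle(x)))
  invisible(x)
}

# Rotation matrix with rows x, y, z: maps working-frame coordinates to
# frame-local coordinates.
axes_rotation <- function(axes) {
  rbind(axes$x_axis, axes$y_axis, axes$z_axis, deparse.level = 0)
}

#' Estimate the global axes of one volume
#'
#' Convenience wrapper chaining [extract_sphere_roi()], [determine_y_axis()],
#' [project_binarize()], [determine_x_axis()] and [complete_axes()].
#'
#' @param mask a `skull_mask`.
#' @param tip a `nose_tip`.
#' @param radius sphere radius in mm (default 35).
#' @param pixel_mm projection raster in mm (default 1).
#' @return A `global_axes`.
#' @export
estimate_axes <- function(mask, tip, radius = 35, pixel_mm = 1) {
  roi <- extract_sphere_roi(mask, tip, radius)
  y <- determine_y_axis(roi)
  proj <- project_binarize(roi, y, pixel_mm)
  x <- determine_x_axis(proj)
  pca <- pca_axes(roi)
  complete_axes(x, y, tip, eigenvalues = pca$values)
}

#' Resample a volume into its global axes
#'
#' The output grid keeps the input spacing and field of view; output lattice
#' axes run along the estimated head axes and the rotation is applied about
#' the nose tip (the frame origin), so the tip keeps its working-frame
#' position. Out-of-field voxels get the `background` value.
#'
#' @param volume a [voxel_volume()] (or `skull_mask`).
#' @param axes a `global_axes`.
#' @param interpolation `"linear"` (intensities) or `"nearest"` (masks).
#' @param background fill value outside the input field of view (default 0).
#' @return A [voxel_volume()] on the same lattice; logical input yields
#'   logical output.
#' @export
reorient_volume <- function(volume, axes,
                            interpolation = c("linear", "nearest"),
                            background = 0) {
  stopifnot(is_voxel_volume(volume), inherits(axes, "global_axes"))
  interpolation <- match.arg(interpolation)
  was_logical <- is.logical(volume$data)
  R <- axes_rotation(axes)
  # output voxel i sits at new-frame offset g_i - tip (g_i = input lattice mm);
  # its world sample position is tip + t(R) %*% (g_i - tip)
  S_out <- diag(volume$spacing)
  S_in_inv <- diag(1 / volume$spacing)
  M <- S_in_inv %*% t(R) %*% S_out
  tip <- axes$origin
  off0 <- tip + as.numeric(t(R) %*% (volume$origin - tip)) # world pos of out voxel 0
  off <- as.numeric(S_in_inv %*% (off0 - volume$origin))   # in input index units
  dat <- volume$data
  if (was_logical) storage.mode(dat) <- "double"
  out <- .resample_affine(dat, dim(dat), dim(dat), M, off,
                          interpolation == "linear", background)
  if (was_logical) out <- array(out > 0.5, dim(out))
  res <- voxel_volume(out, spacing = volume$spacing, origin = volume$origin,
                      axes = "LAS")
  if (is_skull_mask(volume)) class(res) <- c("skull_mask", class(res))
  res
}

#' Net rotation of a global frame, in degrees
#'
#' Angle of the rotation taking the working frame onto the estimated frame:
#' `theta = acos((trace(R) - 1) / 2)`, in `[0, 180]` degrees.
#'
#' @param axes a `global_axes`, or a 3x3 rotation matrix.
#' @return Angle in degrees.
#' @export
rotation_angle <- function(axes) {
  R <- if (inherits(axes, "global_axes")) axes_rotation(axes) else as.matrix(axes)
  tr <- sum(diag(R))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}
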