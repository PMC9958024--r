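#' Frontal (x-z) silhouette of a skull mask
#'
#' Projects the mask along the anteroposterior axis: pixel `(x, z)` is on iff
#' any voxel in the y-column at that `(x, z)` is foreground.
#'
#' @param mask a `skull_mask` (see [segment_skull()]).
#' @return A list with `image` (nx x nz logical matrix), `x_mm` and `z_mm`
#'   (pixel-centre coordinates), of class `frontal_projection`.
#' @export
render_frontal <- function(mask) {
  stopifnot(is_voxel_volume(mask))
  arr <- mask$data
  if (!any(arr)) stop("empty mask", call. = FALSE)
  img <- colSums(aperm(arr, c(2, 1, 3))) > 0
  dims <- dim(arr)
  structure(
    list(
      image = img,
      x_mm = mask$origin[1] + (seq_len(dims[1]) - 1) * mask$spacing[1],
      z_mm = mask$origin[3] + (seq_len(dims[3]) - 1) * mask$spacing[3]
    ),
    class = "frontal_projection"
  )
}

#' Automatic naso-orbital ROI on the frontal silhouette
#'
#' The naso-orbital region sits mid-face: the ROI spans the central 30% of
#' the silhouette's transverse extent and the band from 40% to 70% of its
#' height measured down from the top. Both fractions are heuristics for adult
#' head anatomy and can be overridden by passing an explicit ROI to
#' [detect_nose_tip()].
#'
#' @param projection a `frontal_projection` from [render_frontal()].
#' @return A list `nose_roi` with `x_range` and `z_range` in mm.
#' @export
auto_nose_roi <- function(projection) {
  img <- projection$image
  on_x <- which(apply(img, 1, any))
  on_z <- which(apply(img, 2, any))
  if (length(on_x) < 10 || length(on_z) < 10) {
    stop("silhouette too small for automatic ROI placement", call. = FALSE)
  }
  x_lo <- projection$x_mm[min(on_x)]
  x_hi <- projection$x_mm[max(on_x)]
  z_lo <- projection$z_mm[min(on_z)]
  z_hi <- projection$z_mm[max(on_z)]
  width <- x_hi - x_lo
  height <- z_hi - z_lo
  structure(
    list(
      x_range = c(x_lo + 0.35 * width, x_lo + 0.65 * width),
      z_range = c(z_hi - 0.70 * height, z_hi - 0.40 * height)
    ),
    class = "nose_roi"
  )
}

nose_roi <- function(x_range, z_range) {
  stopifnot(length(x_range) == 2, length(z_range) == 2,
            x_range[1] < x_range[2], z_range[1] < z_range[2])
  structure(list(x_range = as.numeric(x_range), z_range = as.numeric(z_range)),
            class = "nose_roi")
}

#' Convex-hull vertices of a point cloud
#'
#' Vertex coordinates of the 3D convex hull, computed by an incremental
#' quickhull. Points interior to the hull (or interior to a face or edge) are
#' not vertices.
#'
#' @param points N x 3 numeric matrix.
#' @return Integer vector of row indices of `points` that are hull vertices.
#' @export
convex_hull_vertices <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  .hull3d_vertices(points)
}

#' Detect the nose tip from a skull mask
#'
#' The skull surface is concave over most of the face, so the anterior
#' convex hull touches the skull only near the nasal apex; the hull vertices
#' whose frontal coordinates fall inside the naso-orbital ROI therefore
#' cluster at the nose. Among those vertices, all lying within
#' `apex_band_mm` of the most anterior one are averaged, which stabilizes
#' the tip against single-voxel noise.
#'
#' When `roi = NULL` the ROI is placed automatically with [auto_nose_roi()]
#' and then refined once: the same-size window is re-centred on the first
#' detection and the detection repeated. Under a large head yaw the apex can
#' swing to the edge of the silhouette-fraction window, which would clip the
#' averaging band one-sidedly; the fixed-point re-centring removes that bias
#' without using any prior knowledge of the anatomy.
#'
#' @param mask a `skull_mask`.
#' @param roi a `nose_roi`, or `NULL` to place it automatically with
#'   [auto_nose_roi()].
#' @param apex_band_mm depth of the anterior band that is averaged (default
#'   2 mm).
#' @return A `nose_tip`: list with `position` (mm, working frame) and
#'   `support_count` (number of hull vertices averaged).
#' @export
detect_nose_tip <- function(mask, roi = NULL, apex_band_mm = 2) {
  stopifnot(is_voxel_volume(mask), apex_band_mm > 0)
  auto <- is.null(roi)
  if (auto) roi <- auto_nose_roi(render_frontal(mask))
  surf <- surface_mask(mask$data)
  pts <- mask_points_mm(surf, mask$spacing, mask$origin)
  if (nrow(pts) < 4) stop("mask too small for hull computation", call. = FALSE)
  hull_idx <- convex_hull_vertices(pts)
  hv <- pts[hull_idx, , drop = FALSE]
  tip_in_roi <- function(roi) {
    sel <- hv[, 1] >= roi$x_range[1] & hv[, 1] <= roi$x_range[2] &
      hv[, 3] >= roi$z_range[1] & hv[, 3] <= roi$z_range[2]
    if (!any(sel)) {
      stop("no convex-hull vertex inside the naso-orbital ROI; check ROI placement",
           call. = FALSE)
    }
    cand <- hv[sel, , drop = FALSE]
    y_star <- max(cand[, 2])
    keep <- cand[, 2] >= y_star - apex_band_mm
    structure(
      list(position = as.numeric(colMeans(cand[keep, , drop = FALSE])),
           support_count = sum(keep)),
      class = "nose_tip"
    )
  }
  if (auto) {
    # Pass 1: within the naso-orbital z band the nasal projection is the
    # anterior-most bone by definition, so search the full transverse
    # extent first; a large head yaw can otherwise swing the apex outside
    # the central silhouette window, whose interior anterior maximum is the
    # cranial pole, not the nose.
    wide <- nose_roi(range(hv[, 1]) + c(-1, 1), roi$z_range)
    tip1 <- tip_in_roi(wide)
    # Pass 2: the spec-size window re-centred on the first detection.
    roi <- nose_roi(
      tip1$position[1] + c(-0.5, 0.5) * diff(roi$x_range),
      tip1$position[3] + c(-0.5, 0.5) * diff(roi$z_range)
    )
  }
  tip_in_roi(roi)
}

#' @export
print.nose_tip <- function(x, ...) {
  cat(sprintf("<nose_tip> (%.2f, %.2f, %.2f) mm from %d hull vertices\n",
              x$position[1], x$position[2], x$position[3], x$support_count))
  invisible(x)
}
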