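#' Extract the forehead surface above the nose tip
#'
#' Anterior-facing surface voxels (foreground with a background 6-neighbour
#' in +y) inside the band `z in [tip_z + z_lo, tip_z + z_hi]`, over the full
#' transverse extent, keeping per (x, z) column only the most anterior one.
#' The column rule selects the exterior front surface that a frontal
#' rendering sees: without it the set also contains the posterior skull
#' wall's inner surface (which faces the cranial cavity, i.e. anteriorly),
#' and the Hausdorff distance then reflects occipital field-of-view
#' differences at a ~20 cm lever arm rather than forehead alignment. The
#' default band of +20..+70 mm above the tip sits above the orbits and
#' below the vertex on adult anatomy.
#'
#' @param mask a `skull_mask`.
#' @param tip `nose_tip` or length-3 mm position.
#' @param z_lo,z_hi band limits in mm above the tip (defaults 20 and 70).
#' @param y_depth posterior depth of the box below the tip's anterior level
#'   (default 80 mm): voxels with `y < tip_y - y_depth` are outside the
#'   forehead box. This bounds the box in the anteroposterior direction so
#'   that posterior and far-lateral skull walls (whose cavity-facing
#'   surfaces also point anteriorly) cannot enter the surface set.
#' @return N x 3 matrix of mm coordinates.
#' @export
extract_forehead <- function(mask, tip, z_lo = 20, z_hi = 70, y_depth = 80) {
  stopifnot(is_voxel_volume(mask), z_lo < z_hi, y_depth > 0)
  tipp <- tip_position(tip)
  surf <- anterior_surface_mask(mask$data)
  idx <- which(surf)
  if (length(idx) == 0) {
    stop("no forehead surface voxels in the requested band", call. = FALSE)
  }
  ai <- arrayInd(idx, dim(mask$data))
  z_mm <- mask$origin[3] + (ai[, 3] - 1) * mask$spacing[3]
  y_mm <- mask$origin[2] + (ai[, 2] - 1) * mask$spacing[2]
  band <- z_mm >= tipp[3] + z_lo & z_mm <= tipp[3] + z_hi &
    y_mm >= tipp[2] - y_depth
  ai <- ai[band, , drop = FALSE]
  if (nrow(ai) == 0) {
    stop("no forehead surface voxels in the requested band", call. = FALSE)
  }
  ord <- order(ai[, 1], ai[, 3], -ai[, 2])
  ai <- ai[ord, , drop = FALSE]
  first <- !duplicated(ai[, c(1, 3), drop = FALSE])
  ai <- ai[first, , drop = FALSE]
  sweep(sweep(ai - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

#' Hausdorff distance between two point sets
#'
#' `HD(A, B) = max(max_a min_b ||a-b||, max_b min_a ||a-b||)` with the 3D
#' Euclidean norm. Nearest neighbours are found with a kd-tree, so the value
#' equals the brute-force all-pairs computation while scaling to surface-
#' sized point sets.
#'
#' @param A,B N x 3 matrices of mm coordinates.
#' @return Distance in mm.
#' @export
hausdorff <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0 || nrow(B) == 0) {
    stop("Hausdorff distance of an empty point set", call. = FALSE)
  }
  dAB <- max(FNN::get.knnx(B, A, k = 1)$nn.dist)
  dBA <- max(FNN::get.knnx(A, B, k = 1)$nn.dist)
  max(dAB, dBA)
}

#' Matching improvement in percent
#'
#' Percentage reduction of the Hausdorff distance from before to after
#' reorientation; negative when alignment worsened.
#'
#' @param before,after Hausdorff distances in mm; `before` must be > 0.
#' @return Percent improvement.
#' @export
matching_improvement <- function(before, after) {
  if (any(before <= 0)) {
    stop("matching improvement undefined for before <= 0", call. = FALSE)
  }
  (before - after) / before * 100
}

#' Evaluate alignment of a serial triplet
#'
#' For each unordered pair of serial volumes, computes the forehead-surface
#' Hausdorff distance before and after reorientation and the matching
#' improvement. "Before" surfaces come from `masks_before` (conventionally
#' the arrangement-only volumes, isolating the rotational part of the
#' alignment; pass the raw masks to compare against untouched frames) and
#' "after" surfaces from `masks_after`. Both sets of surfaces are expressed
#' relative to their volume's nose tip so that the comparison is
#' tip-arranged in both states.
#'
#' @param masks_before,masks_after lists of `skull_mask` objects (same
#'   length, 2 or 3 volumes).
#' @param tips list of `nose_tip` objects (tip positions are identical
#'   before and after because the rotation is applied about the tip).
#' @param z_lo,z_hi forehead band in mm above the tip.
#' @param before_arranged if `TRUE` (default) the "before" surfaces are also
#'   tip-centred, so the metric isolates the rotational part of the
#'   alignment; `FALSE` compares the untouched frames.
#' @return A data.frame with columns `pair`, `hd_before`, `hd_after`,
#'   `improvement_pct`.
#' @export
evaluate_serial <- function(masks_before, masks_after, tips,
                            z_lo = 20, z_hi = 70, before_arranged = TRUE) {
  n <- length(masks_before)
  stopifnot(n >= 2, length(masks_after) == n, length(tips) == n)
  for (m in masks_after[-1]) {
    if (!identical(dim(m$data), dim(masks_after[[1]]$data)) ||
        !isTRUE(all.equal(m$spacing, masks_after[[1]]$spacing))) {
      stop("mismatched lattices among reoriented volumes", call. = FALSE)
    }
  }
  fore <- function(masks, center) {
    lapply(seq_len(n), function(i) {
      pts <- extract_forehead(masks[[i]], tips[[i]], z_lo, z_hi)
      if (center) pts <- sweep(pts, 2, tip_position(tips[[i]]))
      pts
    })
  }
  fb <- fore(masks_before, center = before_arranged)
  fa <- fore(masks_after, center = TRUE)
  pairs <- utils::combn(n, 2)
  labels <- paste0("T", pairs[1, ] - 1, "T", pairs[2, ] - 1)
  hd_before <- hd_after <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    hd_before[p] <- hausdorff(fb[[i]], fb[[j]])
    hd_after[p] <- hausdorff(fa[[i]], fa[[j]])
  }
  data.frame(
    pair = labels,
    hd_before = hd_before,
    hd_after = hd_after,
    improvement_pct = ifelse(hd_before > 0,
                             (hd_before - hd_after) / hd_before * 100,
                             NA_real_)
  )
}
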