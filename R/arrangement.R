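#' Rigid transform
#'
#' A rotation about a stated centre followed by a translation:
#' `p -> R (p - center) + center + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 mm translation.
#' @param center length-3 mm rotation centre (default the origin).
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be a proper orthonormal 3x3 matrix", call. = FALSE)
  }
  structure(
    list(rotation = rotation, translation = as.numeric(translation),
         center = as.numeric(center)),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points N x 3 matrix or length-3 vector of mm coordinates.
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_rigid <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- matrix(as.numeric(points), ncol = 3, byrow = vec)
  out <- sweep(p, 2, transform$center) %*% t(transform$rotation)
  out <- sweep(out, 2, transform$center + transform$translation, `+`)
  if (vec) as.numeric(out) else out
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`,
#' expressed about the origin.
#'
#' @param second,first [rigid_transform()] objects.
#' @return A [rigid_transform()] with centre at the origin.
#' @export
compose_rigid <- function(second, first) {
  R <- second$rotation %*% first$rotation
  # express both about the origin: p -> R p + t
  t1 <- first$translation + first$center -
    as.numeric(first$rotation %*% first$center)
  t2 <- second$translation + second$center -
    as.numeric(second$rotation %*% second$center)
  rigid_transform(R, as.numeric(second$rotation %*% t1) + t2)
}

#' Rotation matrix from per-axis angles
#'
#' Builds `Rz %*% Ry %*% Rx` from rotations about the working x, y and z
#' axes, in degrees.
#'
#' @param angles_deg length-3 rotation angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_angles <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Intermediary arrangement of serial volumes on the nose tip
#'
#' Before axes exist there is no rotational reference, so the arrangement is
#' translation-only: each volume is translated so its nose tip lands on the
#' working-frame origin. Using the origin (rather than the first volume's
#' tip) as the common reference keeps each volume's processing independent
#' of acquisition order.
#'
#' @param tips list of `nose_tip` objects (one per serial volume).
#' @return List of [rigid_transform()] pure translations.
#' @export
arrange <- function(tips) {
  if (inherits(tips, "nose_tip")) tips <- list(tips)
  if (length(tips) == 0) stop("no volumes to arrange", call. = FALSE)
  lapply(tips, function(tip) {
    stopifnot(inherits(tip, "nose_tip"))
    rigid_transform(diag(3), -tip$position)
  })
}

# Shift a volume's origin (translation-only arrangement needs no resampling).
translate_volume <- function(volume, translation) {
  volume$origin <- volume$origin + as.numeric(translation)
  volume
}
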