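#' Otsu's threshold of an intensity distribution
#'
#' Builds an `nbins`-bin histogram over the intensity range and returns the
#' interior bin edge that maximizes the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}, where class 0 holds values
#' strictly below the edge. Ties are broken towards the lowest edge.
#'
#' @param x numeric vector or array of intensities (a [voxel_volume()] is
#'   also accepted).
#' @param nbins number of histogram bins (default 256).
#' @return The threshold, a single number on the intensity scale.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  if (is_voxel_volume(x)) x <- x$data
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2 || rng[1] == rng[2]) {
    stop("cannot threshold a constant intensity distribution", call. = FALSE)
  }
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  bin <- findInterval(v, edges, all.inside = TRUE)
  counts <- tabulate(bin, nbins)
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * centers)
  total_n <- w0[nbins]
  total_m <- m0[nbins]
  # candidate thresholds: interior edges edges[2..nbins]; class 0 = bins 1..t
  t <- seq_len(nbins - 1)
  n0 <- w0[t]; n1 <- total_n - n0
  valid <- n0 > 0 & n1 > 0
  bcv <- rep(-Inf, nbins - 1)
  mu0 <- m0[t][valid] / n0[valid]
  mu1 <- (total_m - m0[t][valid]) / n1[valid]
  bcv[valid] <- (n0[valid] / total_n) * (n1[valid] / total_n) *
    (mu0 - mu1)^2
  edges[which.max(bcv) + 1]
}

# Exhaustive two-threshold (three-class) Otsu: maximizes the between-class
# variance of an air / soft-tissue / bone decomposition and returns the two
# bin edges. Sequential binary Otsu is order-unstable on trimodal CBCT
# histograms (whichever boundary has the larger contrast is found first),
# so both thresholds are searched jointly.
otsu_thresholds3 <- function(x, nbins = 256) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 3 || rng[1] == rng[2]) {
    stop("cannot threshold a constant intensity distribution", call. = FALSE)
  }
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  counts <- tabulate(findInterval(v, edges, all.inside = TRUE), nbins)
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  W <- cumsum(counts)
  M <- cumsum(counts * centers)
  n <- W[nbins]; mt <- M[nbins]
  # classes: bins 1..i, i+1..j, j+1..nbins for 1 <= i < j <= nbins-1
  term <- function(wlo, mlo, whi, mhi) {
    w <- whi - wlo
    ifelse(w > 0, (mhi - mlo)^2 / w, 0)
  }
  f1 <- term(0, 0, W, M)                       # class 1 ending at i
  best <- -Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(nbins - 2)) {
    j <- (i + 1):(nbins - 1)
    f <- f1[i] + term(W[i], M[i], W[j], M[j]) + term(W[j], M[j], n, mt)
    k <- which.max(f)
    if (f[k] > best) { best <- f[k]; bi <- i; bj <- j[k] }
  }
  c(edges[bi + 1], edges[bj + 1])
}

#' Segment the dentoskeletal region
#'
#' Thresholds the volume at the bone intensity, keeps the largest
#' 26-connected component (which removes headrest/table artifacts and
#' detached noise), and closes the mask with a 1-voxel-radius ball. By
#' default the bone threshold is the upper edge of a three-class Otsu
#' decomposition of the intensity histogram into air, soft tissue and bone,
#' eliminating noise and soft tissue in one pass; CBCT histograms are
#' roughly trimodal and a single global threshold can land on either
#' boundary. Use `two_pass = FALSE` for a single global Otsu threshold.
#'
#' @param volume a [voxel_volume()] in the working frame.
#' @param nbins histogram bins for Otsu (default 256).
#' @param two_pass logical; three-class air/soft/bone thresholding
#'   (default TRUE), otherwise a single binary Otsu threshold.
#' @return A `skull_mask`: a [voxel_volume()] whose `data` is logical, with
#'   the bone threshold in attribute `"threshold"`.
#' @export
segment_skull <- function(volume, nbins = 256, two_pass = TRUE) {
  stopifnot(is_voxel_volume(volume))
  thr <- if (two_pass) {
    otsu_thresholds3(volume$data, nbins)[2]
  } else {
    otsu_threshold(volume$data, nbins)
  }
  mask <- volume$data >= thr
  if (!any(mask)) stop("empty mask after thresholding", call. = FALSE)
  dims <- dim(volume$data)
  mask <- .largest_component_26(mask, dims)
  mask <- .morph_cross(.morph_cross(mask, dims, 1L), dims, 0L)
  out <- voxel_volume(mask, spacing = volume$spacing, origin = volume$origin,
                      axes = volume$axes)
  class(out) <- c("skull_mask", class(out))
  attr(out, "threshold") <- thr
  out
}

is_skull_mask <- function(x) inherits(x, "skull_mask")

as_skull_mask <- function(mask_array, like) {
  out <- voxel_volume(mask_array, spacing = like$spacing, origin = like$origin,
                      axes = like$axes)
  class(out) <- c("skull_mask", class(out))
  out
}

# Surface voxels: foreground with at least one 6-neighbour background voxel
# (the grid border counts as background).
surface_mask <- function(mask_array) {
  eroded <- .morph_cross(mask_array, dim(mask_array), 0L)
  mask_array & !eroded
}

# Foreground voxels whose +y 6-neighbour is background: the anterior-facing
# part of the surface.
anterior_surface_mask <- function(mask_array) {
  dims <- dim(mask_array)
  shifted <- array(FALSE, dims)
  shifted[, seq_len(dims[2] - 1), ] <- mask_array[, 2:dims[2], , drop = FALSE]
  mask_array & !shifted
}
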