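#' Voxel volume container
#'
#' A `voxel_volume` is a 3D scalar grid with physical metadata: voxel spacing
#' in mm along each lattice axis, the mm position of voxel `(1,1,1)` (stored
#' 0-based internally, i.e. of index `(0,0,0)`), and a three-letter anatomical
#' orientation code giving the patient direction of increasing index along
#' each array axis (letters from `L/R`, `A/P`, `S/I`). World coordinates are
#' always expressed in the package working frame: `+x` patient-left, `+y`
#' anterior, `+z` superior, i.e. code `"LAS"`.
#'
#' @param data 3D numeric (or logical) array; each dimension must be >= 2.
#' @param spacing numeric length-3, mm per voxel, strictly positive.
#' @param origin numeric length-3, mm position (working frame) of voxel
#'   index `(0,0,0)`.
#' @param axes character orientation code such as `"LAS"`, `"RAS"`, `"PIL"`;
#'   one letter per array axis, jointly covering the three anatomical axis
#'   pairs. `NA` marks an unknown orientation (e.g. a headerless import).
#' @return An object of class `voxel_volume`.
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' dim(v$data)
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         axes = "LAS") {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 2L)) {
    stop("each dimension of `data` must be >= 2", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  }
  if (!is.na(axes)) check_axis_code(axes)
  structure(
    list(data = data, spacing = spacing, origin = origin, axes = axes),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, axes %s\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    x$spacing[1], x$spacing[2], x$spacing[3],
    if (is.na(x$axes)) "unknown" else x$axes
  ))
  cat(sprintf(
    "  origin (%.2f, %.2f, %.2f) mm, intensity range [%.4g, %.4g]\n",
    x$origin[1], x$origin[2], x$origin[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

is_voxel_volume <- function(x) inherits(x, "voxel_volume")

# Letters -> signed working-frame axis: value k means axis |k| with sign(k).
axis_letter_to_dir <- c(L = 1, R = -1, A = 2, P = -2, S = 3, I = -3)

check_axis_code <- function(axes) {
  if (!is.character(axes) || length(axes) != 1L || nchar(axes) != 3L) {
    stop("orientation code must be a 3-letter string such as \"LAS\"",
         call. = FALSE)
  }
  letters3 <- strsplit(toupper(axes), "")[[1]]
  dirs <- axis_letter_to_dir[letters3]
  if (any(is.na(dirs)) || length(unique(abs(dirs))) != 3L) {
    stop(sprintf("invalid orientation code \"%s\"", axes), call. = FALSE)
  }
  invisible(as.integer(dirs))
}

#' Map a volume into the working anatomical frame
#'
#' Permutes and flips the array axes so that array axis 1 runs patient-left
#' (`+x`), axis 2 anterior (`+y`), and axis 3 superior (`+z`), updating
#' spacing and origin accordingly. Applying the function to a volume already
#' in the working frame is the identity, so the map is idempotent.
#'
#' @param volume a [voxel_volume()].
#' @param assume optional orientation code used when `volume$axes` is `NA`
#'   (e.g. an anonymized export with stripped orientation metadata).
#' @return A `voxel_volume` with `axes == "LAS"`.
#' @export
to_working_frame <- function(volume, assume = NULL) {
  stopifnot(is_voxel_volume(volume))
  axes <- volume$axes
  if (is.na(axes)) {
    if (is.null(assume)) {
      stop("orientation unknown: supply `assume` (e.g. \"LAS\")", call. = FALSE)
    }
    axes <- assume
  }
  dirs <- check_axis_code(axes)
  if (identical(dirs, 1:3)) {
    out <- volume
    out$axes <- "LAS"
    return(out)
  }
  perm <- match(1:3, abs(dirs)) # perm[k] = source array axis feeding working axis k
  data <- aperm(volume$data, perm)
  spacing <- volume$spacing[perm]
  dims_src <- dim(volume$data)
  origin <- c(0, 0, 0)
  for (k in 1:3) {
    src <- perm[k]
    sgn <- sign(dirs[src])
    n <- dims_src[src]
    if (sgn < 0) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[k]] <- n:1
      data <- do.call(`[`, c(list(data), idx, list(drop = FALSE)))
      # voxel (0,..) of the flipped axis was index n-1; its world coordinate
      # along working axis k is origin_k - (n-1) * spacing
      origin[k] <- volume$origin[k] - (n - 1) * spacing[k]
    } else {
      origin[k] <- volume$origin[k]
    }
  }
  voxel_volume(data, spacing = spacing, origin = origin, axes = "LAS")
}

# mm coordinates (working frame) of 1-based voxel indices in an LAS volume.
voxel_to_mm <- function(volume, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, volume$spacing, `*`), 2, volume$origin, `+`)
}

# mm coordinates of all TRUE voxels of a logical array on the volume lattice.
mask_points_mm <- function(mask_array, spacing, origin) {
  idx <- which(mask_array)
  if (length(idx) == 0) {
    return(matrix(numeric(0), ncol = 3))
  }
  ai <- arrayInd(idx, dim(mask_array))
  sweep(sweep((ai - 1), 2, spacing, `*`), 2, origin, `+`)
}
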