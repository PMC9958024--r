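#' Load a volume from NIfTI or NRRD
#'
#' Reads a `.nii`, `.nii.gz` or `.nrrd` file. Spacing, origin and axis
#' orientation come from the header; voxel values are unchanged (up to the
#' file's own scale slope/intercept). The file's world coordinate system is
#' interpreted as the working frame (`+x` left, `+y` anterior, `+z` superior).
#'
#' @param path file path.
#' @return A [voxel_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_nifti(path)
  } else {
    stop("unsupported volume format (use .nii, .nii.gz or .nrrd)",
         call. = FALSE)
  }
}

#' Save a volume to NIfTI or NRRD
#'
#' The header encodes spacing, origin and axis orientation; data are written
#' as 64-bit floats so that [load_volume()] round-trips voxelwise exactly.
#'
#' @param volume a [voxel_volume()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return Invisibly, `path`.
#' @export
save_volume <- function(volume, path) {
  stopifnot(is_voxel_volume(volume))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    stop(sprintf("cannot write to %s", dir), call. = FALSE)
  }
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(volume, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_nifti(volume, path)
  } else {
    stop("unsupported volume format (use .nii, .nii.gz or .nrrd)",
         call. = FALSE)
  }
  invisible(path)
}
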