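# Minimal NIfTI-1 (.nii / .nii.gz) reader and writer, little-endian only.
# The file's world coordinate system is taken to be the package working frame
# (+x left, +y anterior, +z superior); the sform affine encodes spacing,
# origin and axis orientation.

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),
  `4`   = list(what = "integer", size = 2, signed = TRUE),
  `8`   = list(what = "integer", size = 4, signed = TRUE),
  `16`  = list(what = "double",  size = 4, signed = TRUE),
  `64`  = list(what = "double",  size = 8, signed = TRUE),
  `512` = list(what = "integer", size = 2, signed = FALSE)
)

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti <- function(path) {
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header", call. = FALSE)
  rint <- function(off, size, what = "integer", signed = TRUE, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], what,
            size = size, n = n, signed = signed, endian = "little")
  }
  sizeof_hdr <- rint(0, 4)
  if (sizeof_hdr != 348L) {
    stop("not a little-endian NIfTI-1 file (sizeof_hdr != 348)", call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("missing NIfTI magic", call. = FALSE)
  dims <- rint(40, 2, n = 8)
  ndim <- dims[1]
  if (ndim < 3) stop("NIfTI file is not a 3D volume", call. = FALSE)
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  if (ndim > 3 && any(dims[5:(1 + ndim)] > 1)) {
    stop("multi-volume NIfTI files are not supported", call. = FALSE)
  }
  datatype <- rint(70, 2)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype %d", datatype),
                        call. = FALSE)
  pixdim <- rint(76, 4, what = "double", n = 8)
  vox_offset <- rint(108, 4, what = "double")
  scl_slope <- rint(112, 4, what = "double")
  scl_inter <- rint(116, 4, what = "double")
  sform_code <- rint(254, 2)
  srow <- rbind(rint(280, 4, what = "double", n = 4),
                rint(296, 4, what = "double", n = 4),
                rint(312, 4, what = "double", n = 4))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- as.double(nx) * ny * nz
  vals <- readBin(con, dt$what, size = dt$size, n = n, signed = dt$signed,
                  endian = "little")
  if (length(vals) < n) stop("truncated NIfTI data section", call. = FALSE)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  arr <- array(as.numeric(vals), dim = c(nx, ny, nz))
  if (sform_code > 0) {
    geo <- affine_to_geometry(srow[, 1:3], srow[, 4])
  } else {
    geo <- list(spacing = abs(pixdim[2:4]), origin = c(0, 0, 0), axes = "LAS")
  }
  voxel_volume(arr, spacing = geo$spacing, origin = geo$origin,
               axes = geo$axes)
}

write_nifti <- function(volume, path) {
  dims <- dim(volume$data)
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  w <- function(x, size, what = "integer") {
    writeBin(x, con, size = size, endian = "little")
  }
  pad <- function(n) writeBin(raw(n), con)
  w(348L, 4)                                   # sizeof_hdr
  pad(36)                                      # data_type..dim_info
  w(as.integer(c(3, dims, 1, 1, 1, 1)), 2)     # dim[8]
  w(numeric(3), 4)                             # intent_p1..p3
  w(0L, 2)                                     # intent_code
  w(64L, 2)                                    # datatype: float64
  w(64L, 2)                                    # bitpix
  w(0L, 2)                                     # slice_start
  writeBin(as.numeric(c(1, volume$spacing, 0, 0, 0, 0)), con, size = 4,
           endian = "little")                  # pixdim[8]
  writeBin(c(352, 1, 0), con, size = 4, endian = "little") # vox_offset, scl
  w(0L, 2); pad(2)                             # slice_end, slice_code+xyzt
  writeBin(numeric(4), con, size = 4, endian = "little")   # cal/slice_dur/toff
  w(c(0L, 0L), 4)                              # glmax, glmin
  pad(104)                                     # descrip + aux_file
  w(0L, 2)                                     # qform_code
  w(1L, 2)                                     # sform_code
  writeBin(numeric(6), con, size = 4, endian = "little")   # quatern + qoffset
  aff <- geometry_to_affine(volume)
  for (r in 1:3) {
    writeBin(as.numeric(c(aff$A[r, ], aff$b[r])), con, size = 4,
             endian = "little")
  }
  pad(16)                                      # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  pad(4)                                       # extension flag
  writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  invisible(NULL)
}

# 3x3 direction/spacing matrix and offset -> spacing, origin, orientation code.
affine_to_geometry <- function(A, b) {
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0)) stop("degenerate affine in volume header", call. = FALSE)
  codes <- character(3)
  pos <- c("L", "A", "S"); neg <- c("R", "P", "I")
  for (j in 1:3) {
    k <- which.max(abs(A[, j]))
    codes[j] <- if (A[k, j] >= 0) pos[k] else neg[k]
  }
  axes <- paste(codes, collapse = "")
  check_axis_code(axes)
  list(spacing = spacing, origin = as.numeric(b), axes = axes)
}

geometry_to_affine <- function(volume) {
  dirs <- check_axis_code(if (is.na(volume$axes)) "LAS" else volume$axes)
  A <- matrix(0, 3, 3)
  for (j in 1:3) A[abs(dirs[j]), j] <- sign(dirs[j]) * volume$spacing[j]
  list(A = A, b = volume$origin)
}
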