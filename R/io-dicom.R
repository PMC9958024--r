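# Minimal DICOM support: an explicit-VR little-endian single-frame series
# reader covering the tags a CBCT export needs, plus a synthetic series
# writer used to build test fixtures and phantoms on disk. Compressed
# transfer syntaxes and multi-frame enhanced DICOM are out of scope.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

# VRs with a 2-byte reserved field and 4-byte length
dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", n = 132)
  if (length(preamble) < 132 ||
      rawToChar(preamble[129:132]) != "DICM") {
    stop(sprintf("%s: not a DICOM part-10 file", basename(path)),
         call. = FALSE)
  }
  elements <- list()
  repeat {
    grp <- readBin(con, "integer", size = 2, signed = FALSE, endian = "little")
    if (length(grp) == 0) break
    ele <- readBin(con, "integer", size = 2, signed = FALSE, endian = "little")
    vr <- rawToChar(readBin(con, "raw", n = 2))
    if (vr %in% dcm_long_vrs) {
      readBin(con, "raw", n = 2)
      len <- readBin(con, "integer", size = 4, endian = "little")
    } else {
      len <- readBin(con, "integer", size = 2, signed = FALSE,
                     endian = "little")
    }
    if (len < 0) stop("undefined-length DICOM element not supported",
                      call. = FALSE)
    payload <- readBin(con, "raw", n = len)
    if (length(payload) < len) stop("truncated DICOM element", call. = FALSE)
    key <- dcm_tag(grp, ele)
    elements[[key]] <- list(vr = vr, bytes = payload)
    if (identical(key, "7FE0,0010")) break
  }
  elements
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$bytes))
}
dcm_ds <- function(el) {
  s <- dcm_str(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$bytes, "integer", size = 2, signed = FALSE, n = 1,
          endian = "little")
}

#' Read a DICOM series as a voxel volume
#'
#' Reads all single-frame `.dcm` slices in a directory, checks they belong to
#' one series with consistent pixel spacing, sorts them by the projection of
#' `ImagePositionPatient` onto the slice normal, and assembles a
#' [voxel_volume()]. DICOM patient coordinates (LPS) are converted to the
#' working frame (LAS) by flipping the anteroposterior axis.
#'
#' @param directory path containing >= 2 single-frame slices of one series.
#' @return A [voxel_volume()].
#' @seealso [write_dicom_series()] for the synthetic-series writer.
#' @export
load_dicom_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) < 2) {
    stop("need >= 2 DICOM slices to assemble a volume", call. = FALSE)
  }
  slices <- lapply(files, parse_dicom_file)
  uids <- vapply(slices, function(s) dcm_str(s[["0020,000E"]]) %||% "",
                 character(1))
  if (length(unique(uids)) != 1L) {
    stop("mixed SeriesInstanceUID in directory", call. = FALSE)
  }
  first <- slices[[1]]
  rows <- dcm_us(first[["0028,0010"]])
  cols <- dcm_us(first[["0028,0011"]])
  ps <- dcm_ds(first[["0028,0030"]])
  iop <- dcm_ds(first[["0020,0037"]])
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns", call. = FALSE)
  if (is.null(ps) || length(ps) != 2 || any(!is.finite(ps)) || any(ps <= 0)) {
    stop("missing or invalid PixelSpacing", call. = FALSE)
  }
  for (s in slices[-1]) {
    ps2 <- dcm_ds(s[["0028,0030"]])
    if (is.null(ps2) || max(abs(ps2 - ps)) > 1e-6) {
      stop("inconsistent PixelSpacing across slices", call. = FALSE)
    }
  }
  if (is.null(iop)) iop <- c(1, 0, 0, 0, 1, 0)
  row_dir <- iop[1:3]   # direction of increasing column index (LPS)
  col_dir <- iop[4:6]   # direction of increasing row index (LPS)
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  ipp <- lapply(slices, function(s) {
    p <- dcm_ds(s[["0020,0032"]])
    if (is.null(p) || length(p) != 3) {
      stop("missing ImagePositionPatient", call. = FALSE)
    }
    p
  })
  proj <- vapply(ipp, function(p) sum(p * normal), numeric(1))
  ord <- order(proj)
  slices <- slices[ord]; ipp <- ipp[ord]; proj <- proj[ord]
  gaps <- diff(proj)
  if (any(gaps <= 0) || (max(gaps) - min(gaps)) > 1e-3) {
    stop("inconsistent slice positions in series", call. = FALSE)
  }
  dz <- mean(gaps)
  nz <- length(slices)
  arr <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    el <- slices[[k]][["7FE0,0010"]]
    if (is.null(el)) stop("missing PixelData", call. = FALSE)
    bits <- dcm_us(slices[[k]][["0028,0100"]]) %||% 16L
    signed <- (dcm_us(slices[[k]][["0028,0103"]]) %||% 1L) == 1L
    vals <- readBin(el$bytes, "integer", size = bits / 8,
                    n = as.integer(rows) * cols, signed = signed,
                    endian = "little")
    slope <- dcm_ds(slices[[k]][["0028,1053"]]) %||% 1
    inter <- dcm_ds(slices[[k]][["0028,1052"]]) %||% 0
    # pixel data is row-major: column index varies fastest
    arr[, , k] <- matrix(vals * slope + inter, nrow = cols, ncol = rows)
  }
  # LPS -> LAS: negate y of every direction/position
  lps2las <- function(v) c(v[1], -v[2], v[3])
  A <- cbind(lps2las(row_dir) * ps[2],   # column spacing along row direction
             lps2las(col_dir) * ps[1],   # row spacing along column direction
             lps2las(normal) * dz)
  geo <- affine_to_geometry(A, lps2las(ipp[[1]]))
  voxel_volume(arr, spacing = geo$spacing, origin = geo$origin,
               axes = geo$axes)
}

#' Write a voxel volume as a synthetic DICOM series
#'
#' Writes one explicit-VR little-endian single-frame axial slice per z index.
#' This writer exists to build self-contained test fixtures and phantom
#' exports; intensities are rounded to signed 16-bit integers, so volumes
#' with non-integer intensities do not round-trip exactly.
#'
#' @param volume a [voxel_volume()] in the working frame (`"LAS"`).
#' @param directory output directory (created if needed).
#' @param series_uid series UID string; one is generated if omitted.
#' @return Invisibly, the slice file paths.
#' @export
write_dicom_series <- function(volume, directory,
                               series_uid = NULL) {
  stopifnot(is_voxel_volume(volume))
  if (!identical(volume$axes, "LAS")) {
    stop("write_dicom_series expects a working-frame (LAS) volume",
         call. = FALSE)
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(volume$data)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  if (is.null(series_uid)) {
    series_uid <- paste0("1.2.826.0.1.3680043.9999.",
                         format(as.integer(Sys.time())), ".",
                         sample.int(.Machine$integer.max, 1))
  }
  study_uid <- paste0(series_uid, ".0")
  paths <- character(nz)
  for (k in seq_len(nz)) {
    # rows run posterior (+y LPS) => decreasing working y
    slice <- volume$data[, ny:1, k]
    vals <- as.integer(round(as.numeric(slice)))
    if (any(vals > 32767 | vals < -32768)) {
      stop("intensities out of int16 range for DICOM export", call. = FALSE)
    }
    # position of pixel (row 0, col 0) = voxel (0, ny-1, k-1), in LPS
    p0 <- volume$origin +
      c(0, (ny - 1) * volume$spacing[2], (k - 1) * volume$spacing[3])
    ipp <- c(p0[1], -p0[2], p0[3])
    path <- file.path(directory, sprintf("slice_%04d.dcm", k))
    con <- file(path, "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    wel_str <- function(grp, ele, vr, value) {
      bytes <- charToRaw(value)
      if (length(bytes) %% 2 == 1) {
        bytes <- c(bytes, if (vr == "UI") raw(1) else charToRaw(" "))
      }
      writeBin(as.integer(c(grp, ele)), con, size = 2, endian = "little")
      writeBin(charToRaw(vr), con)
      writeBin(length(bytes), con, size = 2, endian = "little")
      writeBin(bytes, con)
    }
    wel_us <- function(grp, ele, value) {
      writeBin(as.integer(c(grp, ele)), con, size = 2, endian = "little")
      writeBin(charToRaw("US"), con)
      writeBin(2L, con, size = 2, endian = "little")
      writeBin(as.integer(value), con, size = 2, endian = "little")
    }
    ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")
    wel_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    wel_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7")
    wel_str(0x0008, 0x0018, "UI", sprintf("%s.%d", series_uid, k))
    wel_str(0x0020, 0x000D, "UI", study_uid)
    wel_str(0x0020, 0x000E, "UI", series_uid)
    wel_str(0x0020, 0x0013, "IS", as.character(k))
    wel_str(0x0020, 0x0032, "DS", ds(ipp))
    wel_str(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0)))
    wel_us(0x0028, 0x0002, 1L)
    wel_us(0x0028, 0x0010, ny)                         # Rows
    wel_us(0x0028, 0x0011, nx)                         # Columns
    wel_str(0x0028, 0x0030, "DS",
            ds(c(volume$spacing[2], volume$spacing[1]))) # row\col spacing
    wel_us(0x0028, 0x0100, 16L)
    wel_us(0x0028, 0x0101, 16L)
    wel_us(0x0028, 0x0102, 15L)
    wel_us(0x0028, 0x0103, 1L)
    wel_str(0x0028, 0x1052, "DS", "0")
    wel_str(0x0028, 0x1053, "DS", "1")
    # PixelData, OW with 4-byte length
    writeBin(as.integer(c(0x7FE0, 0x0010)), con, size = 2, endian = "little")
    writeBin(charToRaw("OW"), con)
    writeBin(raw(2), con)
    writeBin(as.integer(length(vals) * 2), con, size = 4, endian = "little")
    writeBin(vals, con, size = 2, endian = "little")
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}
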