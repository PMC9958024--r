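# Minimal NRRD reader/writer (detached headers not supported). Data written
# as raw little-endian doubles; gzip-encoded files are also readable.

nrrd_types <- list(
  "double" = list(what = "double", size = 8, signed = TRUE),
  "float"  = list(what = "double", size = 4, signed = TRUE),
  "short"  = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "int"    = list(what = "integer", size = 4, signed = TRUE),
  "uchar"  = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE)
)

nrrd_space_flips <- list(
  "left-anterior-superior"  = c(1, 1, 1),
  "las"                     = c(1, 1, 1),
  "right-anterior-superior" = c(-1, 1, 1),
  "ras"                     = c(-1, 1, 1),
  "left-posterior-superior" = c(1, -1, 1),
  "lps"                     = c(1, -1, 1)
)

parse_nrrd_vectors <- function(txt) {
  m <- regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1]]
  lapply(m, function(s) {
    as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  })
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file", call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated NRRD header", call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    fields[[key]] <- trimws(sub("^[^:]+:=?", "", line))
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop(sprintf("NRRD header missing '%s'", k),
                                   call. = FALSE)
    fields[[k]]
  }
  if (as.integer(need("dimension")) != 3L) {
    stop("only 3D NRRD volumes are supported", call. = FALSE)
  }
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- nrrd_types[[tolower(need("type"))]]
  if (is.null(type)) stop("unsupported NRRD type", call. = FALSE)
  encoding <- tolower(need("encoding"))
  endian <- tolower(fields[["endian"]] %||% "little")
  if (endian != "little") stop("big-endian NRRD not supported", call. = FALSE)
  flip <- c(1, 1, 1)
  if (!is.null(fields[["space"]])) {
    flip <- nrrd_space_flips[[tolower(fields[["space"]])]]
    if (is.null(flip)) stop("unsupported NRRD space", call. = FALSE)
  }
  spacing <- rep(1, 3); origin <- c(0, 0, 0); axes <- "LAS"
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    if (length(dirs) != 3) stop("bad 'space directions'", call. = FALSE)
    A <- sweep(do.call(cbind, dirs), 1, flip, `*`)
    b <- c(0, 0, 0)
    if (!is.null(fields[["space origin"]])) {
      b <- parse_nrrd_vectors(fields[["space origin"]])[[1]] * flip
    }
    geo <- affine_to_geometry(A, b)
    spacing <- geo$spacing; origin <- geo$origin; axes <- geo$axes
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- abs(as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]]))
  }
  n <- prod(as.double(sizes))
  if (encoding == "raw") {
    vals <- readBin(con, type$what, size = type$size, n = n,
                    signed = type$signed, endian = "little")
  } else if (encoding %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.size(path))
    raw <- memDecompress(comp, type = "gzip")
    vals <- readBin(raw, type$what, size = type$size, n = n,
                    signed = type$signed, endian = "little")
  } else {
    stop("unsupported NRRD encoding", call. = FALSE)
  }
  if (length(vals) < n) stop("truncated NRRD data", call. = FALSE)
  voxel_volume(array(as.numeric(vals), dim = sizes), spacing = spacing,
               origin = origin, axes = axes)
}

write_nrrd <- function(volume, path) {
  aff <- geometry_to_affine(volume)
  dirvec <- function(j) sprintf("(%.17g,%.17g,%.17g)", aff$A[1, j],
                                aff$A[2, j], aff$A[3, j])
  hdr <- c(
    "NRRD0004",
    "# generated by cbctreorient",
    "type: double",
    "dimension: 3",
    "space: left-anterior-superior",
    paste("sizes:", paste(dim(volume$data), collapse = " ")),
    paste("space directions:", dirvec(1), dirvec(2), dirvec(3)),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)", volume$origin[1],
            volume$origin[2], volume$origin[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(volume$data), con, size = 8, endian = "little")
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
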