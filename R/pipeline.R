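#' Pipeline configuration
#'
#' Collects every tunable of the reorientation workflow with its default.
#' All lengths are mm.
#'
#' @param radius sphere-ROI radius around the nose tip (35).
#' @param nbins Otsu histogram bins (256).
#' @param two_pass two-pass Otsu segmentation (TRUE).
#' @param roi optional fixed naso-orbital ROI, `c(x0, x1, z0, z1)` mm;
#'   `NULL` places it automatically.
#' @param apex_band apex averaging band depth (2).
#' @param pixel_mm projection raster (1).
#' @param z_band forehead band above the tip, `c(lo, hi)` (c(20, 70)).
#' @param interpolation intensity resampling, `"linear"` or `"nearest"`.
#' @param before_mode `"arranged"` (tips matched, no rotation) or `"raw"`
#'   for the pre-reorientation state used in evaluation.
#' @param seed integer seed recorded with reports.
#' @return A `run_config` list.
#' @export
run_config <- function(radius = 35, nbins = 256, two_pass = TRUE, roi = NULL,
                       apex_band = 2, pixel_mm = 1, z_band = c(20, 70),
                       interpolation = "linear",
                       before_mode = c("arranged", "raw"), seed = 0L) {
  before_mode <- match.arg(before_mode)
  stopifnot(radius > 0, nbins >= 2, apex_band > 0, pixel_mm > 0,
            length(z_band) == 2, z_band[1] < z_band[2])
  structure(
    list(radius = radius, nbins = nbins, two_pass = two_pass, roi = roi,
         apex_band = apex_band, pixel_mm = pixel_mm, z_band = z_band,
         interpolation = interpolation, before_mode = before_mode,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Save / load a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals[!vapply(vals, is.null, logical(1))])
}

#' Process one volume: segment, find the tip, estimate axes, reorient
#'
#' @param volume a [voxel_volume()] in the working frame.
#' @param config a [run_config()].
#' @return List with `mask`, `tip`, `axes`, `rotation_deg`,
#'   `reoriented` (volume) and `reoriented_mask`.
#' @export
process_volume <- function(volume, config = run_config()) {
  stopifnot(is_voxel_volume(volume))
  mask <- segment_skull(volume, nbins = config$nbins,
                        two_pass = config$two_pass)
  roi <- if (is.null(config$roi)) NULL else {
    nose_roi(config$roi[1:2], config$roi[3:4])
  }
  tip <- detect_nose_tip(mask, roi = roi, apex_band_mm = config$apex_band)
  axes <- estimate_axes(mask, tip, radius = config$radius,
                        pixel_mm = config$pixel_mm)
  list(
    mask = mask,
    tip = tip,
    axes = axes,
    rotation_deg = rotation_angle(axes),
    reoriented = reorient_volume(volume, axes,
                                 interpolation = config$interpolation),
    reoriented_mask = reorient_volume(mask, axes, interpolation = "nearest")
  )
}

#' Run the full serial reorientation workflow
#'
#' Processes 1-3 serial volumes independently (segmentation, nose tip,
#' arrangement, PCA axes, reorientation) and, when at least two volumes are
#' given, scores pairwise alignment by the forehead-surface Hausdorff
#' distance before and after reorientation.
#'
#' @param volumes list of [voxel_volume()] objects (or file paths readable by
#'   [load_volume()]), in acquisition order T0, T1, T2.
#' @param config a [run_config()].
#' @return A `serial_report`: list with `per_volume` (one [process_volume()]
#'   result each, plus `arranged` translation transforms) and `pairs` (the
#'   [evaluate_serial()] data.frame, `NULL` for a single volume).
#' @export
reorient_serial <- function(volumes, config = run_config()) {
  if (is_voxel_volume(volumes)) volumes <- list(volumes)
  if (length(volumes) == 0) stop("no input volumes", call. = FALSE)
  volumes <- lapply(volumes, function(v) {
    if (is.character(v)) v <- load_volume(v)
    if (!identical(v$axes, "LAS")) v <- to_working_frame(v)
    v
  })
  per <- lapply(volumes, process_volume, config = config)
  tips <- lapply(per, `[[`, "tip")
  arranged <- arrange(tips)
  for (i in seq_along(per)) per[[i]]$arranged <- arranged[[i]]
  pairs <- NULL
  if (length(per) >= 2) {
    pairs <- evaluate_serial(
      masks_before = lapply(per, `[[`, "mask"),
      masks_after = lapply(per, `[[`, "reoriented_mask"),
      tips = tips,
      z_lo = config$z_band[1], z_hi = config$z_band[2],
      before_arranged = config$before_mode == "arranged"
    )
  }
  structure(list(per_volume = per, pairs = pairs, config = config),
            class = "serial_report")
}

#' @export
print.serial_report <- function(x, ...) {
  cat(sprintf("<serial_report> %d volume(s)\n", length(x$per_volume)))
  for (i in seq_along(x$per_volume)) {
    p <- x$per_volume[[i]]
    cat(sprintf("  T%d: tip (%.1f, %.1f, %.1f) mm, rotation %.2f deg\n",
                i - 1, p$tip$position[1], p$tip$position[2],
                p$tip$position[3], p$rotation_deg))
  }
  if (!is.null(x$pairs)) {
    print(x$pairs, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize the per-volume report to JSON
#'
#' Writes tip position, axes, eigenvalues and rotation angle per volume,
#' and the pairwise Hausdorff table, as machine-readable JSON.
#'
#' @param report a `serial_report` from [reorient_serial()].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_serial_report <- function(report, path) {
  out <- list(
    volumes = lapply(seq_along(report$per_volume), function(i) {
      p <- report$per_volume[[i]]
      list(
        label = paste0("T", i - 1),
        tip_mm = p$tip$position,
        tip_support = p$tip$support_count,
        x_axis = p$axes$x_axis,
        y_axis = p$axes$y_axis,
        z_axis = p$axes$z_axis,
        eigenvalues = p$axes$eigenvalues,
        rotation_deg = p$rotation_deg,
        arrangement_translation_mm = p$arranged$translation
      )
    }),
    pairs = report$pairs,
    config = unclass(report$config)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
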