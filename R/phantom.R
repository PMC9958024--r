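# Synthetic head phantom: analytic geometry (quadrics and a wedge) so that
# the bone label map and the nasal apex are exact ground truth, not meshed
# approximations.

#' Head-phantom specification
#'
#' The phantom emulates a binarizable head: an ellipsoidal cranial bone
#' shell, a single anterior paraboloid nasal protrusion with a known apex,
#' two hemispheric orbital concavities carved into the anterior shell, and
#' an inferior mandibular wedge whose tip (the menton) is displaced
#' laterally by `menton_deviation` to model clinical asymmetry. A soft-tissue
#' layer surrounds the bone, and additive Gaussian intensity noise is
#' applied. All lengths are mm, in the working frame centred on the cranial
#' ellipsoid.
#'
#' @param semi_axes cranial ellipsoid semi-axes (x, y, z), mm.
#' @param shell_thickness bone shell thickness, mm.
#' @param nose_apex_z superoinferior offset of the nasal apex from the
#'   ellipsoid centre, mm (defaults to 10% of the z semi-axis below centre,
#'   placing the apex 55% down the frontal silhouette).
#' @param nose_base_radius,nose_length base radius and anterior length of the
#'   nasal paraboloid, mm.
#' @param orbit_offset_x,orbit_offset_z,orbit_radius placement and radius of
#'   the orbital concavities, mm.
#' @param zygoma_offset_x,zygoma_offset_z,zygoma_radius,zygoma_height,zygoma_length
#'   placement (x lateral, z relative to the nasal apex), lateral half-width,
#'   vertical half-height and anterior protrusion of the bilateral
#'   zygomatico-maxillary ridges, mm. These give the spherical-ROI projection
#'   its anatomically defined lateral extremes; without them a smooth shell
#'   projects as a disk bounded by the sphere rim, which carries no
#'   transverse information. The ridges are laterally elongated (height <
#'   width, a sharp lateral margin) so their silhouette extremes rotate with
#'   the anatomy rather than migrating along a circular outline.
#' @param menton_deviation lateral displacement of the mandibular wedge tip
#'   from the midline, mm (the clinical asymmetry magnitude).
#' @param intensities named vector with `air`, `soft`, `bone` mean
#'   intensities (arbitrary units).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param spacing isotropic voxel spacing, mm. The 1 mm default keeps the
#'   volume desk-scale; use 0.39 to match clinical CBCT resolution.
#' @param seed integer seed for the noise realization.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(semi_axes = c(90, 110, 120),
                         shell_thickness = 6,
                         nose_apex_z = -0.1 * semi_axes[3],
                         nose_base_radius = 10,
                         nose_length = 22,
                         orbit_offset_x = 33,
                         orbit_offset_z = 28,
                         orbit_radius = 16,
                         zygoma_offset_x = 26,
                         zygoma_offset_z = -7,
                         zygoma_radius = 8,
                         zygoma_height = 3.5,
                         zygoma_length = 16,
                         menton_deviation = 6,
                         intensities = c(air = 0, soft = 300, bone = 1200),
                         noise_sd = 20,
                         spacing = 1,
                         seed = 0L) {
  if (nose_length <= shell_thickness) {
    stop("invalid spec: nose length must exceed the shell thickness",
         call. = FALSE)
  }
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), spacing > 0,
            shell_thickness > 0, nose_base_radius > 0,
            menton_deviation >= 0, noise_sd >= 0)
  structure(
    list(semi_axes = as.numeric(semi_axes),
         shell_thickness = shell_thickness,
         nose_apex_z = nose_apex_z,
         nose_base_radius = nose_base_radius,
         nose_length = nose_length,
         orbit_offset_x = orbit_offset_x,
         orbit_offset_z = orbit_offset_z,
         orbit_radius = orbit_radius,
         zygoma_offset_x = zygoma_offset_x,
         zygoma_offset_z = zygoma_offset_z,
         zygoma_radius = zygoma_radius,
         zygoma_height = zygoma_height,
         zygoma_length = zygoma_length,
         menton_deviation = menton_deviation,
         intensities = intensities,
         noise_sd = noise_sd,
         spacing = spacing,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# analytic nasal apex of a spec (before any perturbation)
phantom_apex <- function(spec) {
  a <- spec$semi_axes
  y_surf <- a[2] * sqrt(1 - (spec$nose_apex_z / a[3])^2)
  c(0, y_surf + spec$nose_length, spec$nose_apex_z)
}

# full meshgrid arrays for coordinate vectors (x varies fastest)
mesh3 <- function(xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  list(
    X = array(xs, c(nx, ny, nz)),
    Y = array(rep(ys, each = nx), c(nx, ny, nz)),
    Z = array(rep(zs, each = nx * ny), c(nx, ny, nz))
  )
}

#' Generate a head phantom
#'
#' Builds the phantom volume and its ground truth on an isotropic grid that
#' covers the head with a small air margin. The geometry is analytic, so the
#' recorded apex is the exact paraboloid vertex and the bone mask is the
#' exact voxelization of the bone solid. At build time the nasal apex is
#' verified to be the unique anterior maximum of the bone surface within the
#' naso-orbital band.
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [voxel_volume()]) and `truth`
#'   (`phantom_truth`): `bone_mask` (a `skull_mask`), `apex_mm`,
#'   `applied_transform` (identity at generation), `menton_deviation`, and
#'   the noiseless intensity array `clean` used when simulating serial
#'   captures.
#' @export
phantom_generate <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$semi_axes
  s <- spec$spacing
  margin <- 9
  apex <- phantom_apex(spec)
  xs <- seq(-(a[1] + margin), a[1] + margin, by = s)
  ys <- seq(-(a[2] + margin), apex[2] + margin, by = s)
  zs <- seq(-(a[3] + margin), a[3] + margin, by = s)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  origin <- c(xs[1], ys[1], zs[1])
  win <- function(coords, lo, hi) which(coords >= lo & coords <= hi)

  ellipsoid_inside <- function(semi) {
    exy <- outer((xs / semi[1])^2, (ys / semi[2])^2, `+`)
    array(outer(exy, (zs / semi[3])^2, `+`), c(nx, ny, nz)) <= 1
  }
  bone <- ellipsoid_inside(a) & !ellipsoid_inside(a - spec$shell_thickness)

  # nasal paraboloid: apex at `apex`; the cap dips 5 mm below the shell
  # surface at the base radius so the solid overlaps the shell
  rb <- spec$nose_base_radius
  dcap <- (spec$nose_length + 5) / rb^2
  y_anchor <- 0.5 * (apex[2] - spec$nose_length)
  add_nose <- function(mask, rb, dcap, y_top) {
    wx <- win(xs, -rb, rb)
    wy <- win(ys, y_anchor, y_top)
    wz <- win(zs, spec$nose_apex_z - rb, spec$nose_apex_z + rb)
    g <- mesh3(xs[wx], ys[wy], zs[wz])
    rho2 <- g$X^2 + (g$Z - spec$nose_apex_z)^2
    solid <- rho2 <= rb^2 & g$Y <= y_top - dcap * rho2
    mask[wx, wy, wz] <- mask[wx, wy, wz] | solid
    mask
  }
  bone <- add_nose(bone, rb, dcap, apex[2])

  # zygomatico-maxillary ridges: anterior paraboloid bosses lateral-inferior
  # to the nasal apex; their apexes are the projection's lateral extremes
  shell_y <- function(xc, zc) {
    a[2] * sqrt(pmax(0, 1 - (xc / a[1])^2 - (zc / a[3])^2))
  }
  add_boss <- function(mask, xc, zc, rx, rz, len, extra_cap = 0) {
    y_top <- shell_y(xc, zc) + len + extra_cap
    wx <- win(xs, xc - rx, xc + rx)
    wy <- win(ys, shell_y(xc, zc) - 10, y_top)
    wz <- win(zs, zc - rz, zc + rz)
    if (!length(wx) || !length(wy) || !length(wz)) return(mask)
    g <- mesh3(xs[wx], ys[wy], zs[wz])
    rho2 <- ((g$X - xc) / rx)^2 + ((g$Z - zc) / rz)^2
    solid <- rho2 <= 1 & g$Y <= y_top - (len + 5) * rho2
    mask[wx, wy, wz] <- mask[wx, wy, wz] | solid
    mask
  }
  zyg_z <- spec$nose_apex_z + spec$zygoma_offset_z
  for (sx in c(-1, 1)) {
    bone <- add_boss(bone, sx * spec$zygoma_offset_x, zyg_z,
                     spec$zygoma_radius, spec$zygoma_height,
                     spec$zygoma_length)
  }

  # mandibular wedge: cross-section ellipse shrinking towards the menton,
  # whose centre drifts laterally to `menton_deviation`
  wedge_geom <- list(z_base = -0.5 * a[3], z_tip = -(a[3] - 5),
                     rx0 = 48, rx1 = 7, ry0 = 24, ry1 = 7,
                     yc0 = 40, yc1 = 60)
  add_wedge <- function(mask, gpar, grow) {
    zb <- gpar$z_base; zt <- gpar$z_tip + if (grow > 0) -grow else 0
    wx <- win(xs, -(gpar$rx0 + grow) - spec$menton_deviation,
              (gpar$rx0 + grow) + spec$menton_deviation)
    wy <- win(ys, gpar$yc0 - gpar$ry0 - grow, gpar$yc1 + gpar$ry0 + grow)
    wz <- win(zs, zt, zb)
    if (!length(wx) || !length(wy) || !length(wz)) return(mask)
    g <- mesh3(xs[wx], ys[wy], zs[wz])
    t <- pmin(1, pmax(0, (gpar$z_base - g$Z) / (gpar$z_base - gpar$z_tip)))
    rx <- gpar$rx0 + (gpar$rx1 - gpar$rx0) * t + grow
    ry <- gpar$ry0 + (gpar$ry1 - gpar$ry0) * t + grow
    yc <- gpar$yc0 + (gpar$yc1 - gpar$yc0) * t
    xc <- spec$menton_deviation * t
    solid <- ((g$X - xc) / rx)^2 + ((g$Y - yc) / ry)^2 <= 1
    mask[wx, wy, wz] <- mask[wx, wy, wz] | solid
    mask
  }
  bone <- add_wedge(bone, wedge_geom, grow = 0)

  # orbital concavities: carve two spheres centred on the anterior shell
  oy <- a[2] * sqrt(pmax(0, 1 - (spec$orbit_offset_x / a[1])^2 -
                           (spec$orbit_offset_z / a[3])^2))
  for (sx in c(-1, 1)) {
    ctr <- c(sx * spec$orbit_offset_x, oy, spec$orbit_offset_z)
    r <- spec$orbit_radius
    wx <- win(xs, ctr[1] - r, ctr[1] + r)
    wy <- win(ys, ctr[2] - r, ctr[2] + r)
    wz <- win(zs, ctr[3] - r, ctr[3] + r)
    g <- mesh3(xs[wx], ys[wy], zs[wz])
    ball <- (g$X - ctr[1])^2 + (g$Y - ctr[2])^2 + (g$Z - ctr[3])^2 <= r^2
    bone[wx, wy, wz] <- bone[wx, wy, wz] & !ball
  }

  # soft tissue: expanded versions of the solids, minus bone
  soft <- ellipsoid_inside(a + 6)
  soft <- add_nose(soft, rb + 5, (spec$nose_length + 5) / (rb + 5)^2,
                   apex[2] + 4)
  soft <- add_wedge(soft, wedge_geom, grow = 5)
  for (sx in c(-1, 1)) {
    soft <- add_boss(soft, sx * spec$zygoma_offset_x, zyg_z,
                     spec$zygoma_radius + 4, spec$zygoma_height + 4,
                     spec$zygoma_length, extra_cap = 3)
  }
  soft <- soft & !bone

  ints <- spec$intensities
  clean <- array(ints[["air"]], c(nx, ny, nz))
  clean[soft] <- ints[["soft"]]
  clean[bone] <- ints[["bone"]]

  vals <- clean
  if (spec$noise_sd > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(spec$seed)
    vals <- vals + array(rnorm(length(vals), sd = spec$noise_sd),
                         dim(vals))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  volume <- voxel_volume(vals, spacing = rep(s, 3), origin = origin)

  # build-time invariant: the apex is the unique anterior maximum of the
  # bone within the naso-orbital band (central 30% in x, 40-70% down in z)
  bx <- win(xs, -0.3 * a[1], 0.3 * a[1])
  bz <- win(zs, -0.4 * a[3], 0.2 * a[3])
  sub <- bone[bx, , bz]
  stopifnot(any(sub))
  ymax <- ys[max(arrayInd(which(sub), dim(sub))[, 2])]
  # lattice may miss the paraboloid axis by s/2 in x and z, lowering the
  # highest sampled cap voxel by up to dcap * s^2 / 2 below the apex
  if (abs(ymax - apex[2]) > s + dcap * s^2 / 2) {
    stop("phantom invariant violated: nasal apex is not the anterior maximum",
         call. = FALSE)
  }

  truth <- structure(
    list(bone_mask = as_skull_mask(bone, volume),
         apex_mm = apex,
         applied_transform = rigid_transform(),
         menton_deviation = spec$menton_deviation,
         clean = clean,
         spec = spec),
    class = "phantom_truth"
  )
  list(volume = volume, truth = truth)
}

#' Rigidly perturb a phantom (simulate a serial capture)
#'
#' Applies a rigid rotation (degrees about the working axes, about the grid
#' centre) and translation to the noiseless phantom, resamples onto the same
#' grid (linear for intensities, nearest for the truth bone mask), adds a
#' fresh noise realization, and updates the ground truth: the apex is mapped
#' analytically through the transform and `applied_transform` is composed.
#'
#' @param volume the phantom [voxel_volume()].
#' @param truth its `phantom_truth`.
#' @param angles_deg length-3 rotation angles in degrees (|angle| <= 20).
#' @param translation_mm length-3 translation in mm (|t| <= 20).
#' @param seed seed for the fresh noise realization.
#' @param rotation optional 3x3 rotation matrix (net angle <= 25 degrees)
#'   overriding `angles_deg`, e.g. an axis-angle pose.
#' @return List with perturbed `volume` and updated `truth`.
#' @export
phantom_perturb <- function(volume, truth, angles_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0), seed = 0L,
                            rotation = NULL) {
  stopifnot(inherits(truth, "phantom_truth"),
            all(abs(angles_deg) <= 20), all(abs(translation_mm) <= 20))
  R <- if (is.null(rotation)) {
    rotation_from_angles(angles_deg)
  } else {
    stopifnot(rotation_angle(rotation) <= 25)
    rotation
  }
  dims <- dim(volume$data)
  center <- volume$origin + (dims - 1) / 2 * volume$spacing
  tf <- rigid_transform(R, as.numeric(translation_mm), center)
  # output voxel at mm g samples the source at inverse(tf)(g)
  Sp <- diag(volume$spacing)
  Spi <- diag(1 / volume$spacing)
  M <- Spi %*% t(R) %*% Sp
  off0 <- as.numeric(t(R) %*% (volume$origin - center - translation_mm)) +
    center
  off <- as.numeric(Spi %*% (off0 - volume$origin))
  clean <- .resample_affine(truth$clean, dims, dims, M, off, TRUE,
                            truth$spec$intensities[["air"]])
  bone_d <- truth$bone_mask$data
  storage.mode(bone_d) <- "double"
  bone <- .resample_affine(bone_d, dims, dims, M, off, FALSE, 0) > 0.5
  vals <- clean
  sd <- truth$spec$noise_sd
  if (sd > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    vals <- vals + array(rnorm(length(vals), sd = sd), dims)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  new_volume <- voxel_volume(vals, spacing = volume$spacing,
                             origin = volume$origin)
  truth$apex_mm <- apply_rigid(tf, truth$apex_mm)
  truth$applied_transform <- compose_rigid(tf, truth$applied_transform)
  truth$bone_mask <- as_skull_mask(array(bone, dims), new_volume)
  truth$clean <- clean
  list(volume = new_volume, truth = truth)
}

#' Generate a cohort of phantom specifications
#'
#' Draws menton deviations uniformly from each of three severity bands,
#' assigning subjects round-robin across bands, mirroring a cohort whose
#' asymmetry spans mild, moderate and marked magnitudes.
#'
#' @param n number of subjects (>= 3).
#' @param deviation_bands list of three `c(lo, hi)` mm intervals.
#' @param seed RNG seed for the draws.
#' @param ... further arguments passed to [phantom_spec()].
#' @return List of [phantom_spec()] objects; each carries its generating
#'   band index in attribute `"band"`.
#' @export
generate_cohort <- function(n,
                            deviation_bands = list(c(4, 4.5), c(4.5, 9.5),
                                                   c(9.5, 15)),
                            seed = 0L, ...) {
  stopifnot(n >= 3, length(deviation_bands) == 3)
  for (b in deviation_bands) {
    if (length(b) != 2 || b[1] >= b[2]) {
      stop("each deviation band must be a non-empty interval c(lo, hi)",
           call. = FALSE)
    }
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    band <- as.integer((i - 1) %% 3 + 1)
    lim <- deviation_bands[[band]]
    dev <- runif(1, lim[1], lim[2])
    sp <- phantom_spec(menton_deviation = dev, seed = seed + i, ...)
    attr(sp, "band") <- band
    specs[[i]] <- sp
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  specs
}
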