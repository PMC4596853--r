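#' Configuration for a synthetic cord phantom
#'
#' The phantom emulates the imaging situation the segmenter is built for: a
#' darker, gently curved spinal cord surrounded by a bright CSF ring on a
#' mid-intensity tissue background, with an optional cervical-enlargement
#' radius profile, additive Gaussian noise, z-ranges where the CSF signal is
#' obliterated (replaced by tissue), and dark rootlet-like streaks crossing
#' the CSF ring.  All geometry is analytic, so the ground-truth mask and
#' centre line are known exactly.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxel_spacing mm per axis (default 0.3906 x 0.3906 x 0.3).
#' @param amplitude,wavelength sinusoidal in-plane deflection of the centre
#'   line versus z, in mm; `amplitude = 0` gives a straight cord.
#' @param helical if `TRUE` the deflection is helical (x and y) rather than
#'   confined to one sagittal-like plane.
#' @param radius_z,radius_mm knots of the piecewise-linear cord radius
#'   profile: `radius_z` in fractions of the grid z-extent, `radius_mm` in
#'   mm.  The default rises and then falls, mimicking the cervical
#'   enlargement.
#' @param csf_thickness CSF ring thickness in mm.
#' @param edge_softening_mm standard deviation (mm) of the Gaussian blur
#'   applied to the noiseless intensities, emulating partial-volume
#'   averaging and the scanner point-spread function, which spread the
#'   cord/CSF edge of real acquisitions over a few voxels.  Set 0 for
#'   crisp analytic edges.
#' @param intensities named vector with `cord`, `csf` and `tissue` mean
#'   values; CSF is brightest by default, per T2 contrast.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param obliteration_intervals list of `c(z_lo, z_hi)` world-mm ranges
#'   where the CSF ring takes tissue intensity.
#' @param rootlet_artifact_count number of dark streaks crossing the CSF
#'   ring (placed at nerve-rootlet marker locations).
#' @param rootlet_artifact_radius streak radius in mm.
#' @param seed integer controlling the noise realization.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(128L, 128L, 120L),
                           voxel_spacing = c(0.3906, 0.3906, 0.3),
                           amplitude = 2.5, wavelength = 60,
                           helical = FALSE,
                           radius_z = c(0, 0.3, 0.55, 1),
                           radius_mm = c(4.6, 5.0, 5.3, 4.4),
                           csf_thickness = 1.5,
                           edge_softening_mm = 0.35,
                           intensities = c(cord = 60, csf = 160, tissue = 90),
                           noise_sd = 5,
                           obliteration_intervals = list(),
                           rootlet_artifact_count = 0L,
                           rootlet_artifact_radius = 0.4,
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              amplitude = amplitude, wavelength = wavelength,
              helical = helical,
              radius_z = radius_z, radius_mm = radius_mm,
              csf_thickness = csf_thickness,
              edge_softening_mm = edge_softening_mm,
              intensities = intensities, noise_sd = noise_sd,
              obliteration_intervals = obliteration_intervals,
              rootlet_artifact_count = as.integer(rootlet_artifact_count),
              rootlet_artifact_radius = rootlet_artifact_radius,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (any(cfg$voxel_spacing <= 0)) stop("voxel spacings must be positive")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 4L))
    stop("grid_shape must be three counts >= 4")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (cfg$edge_softening_mm < 0) stop("edge_softening_mm must be nonnegative")
  if (any(cfg$radius_mm <= 0)) stop("cord radius must be positive")
  if (is.unsorted(cfg$radius_z)) stop("radius_z knots must be nondecreasing")
  for (iv in cfg$obliteration_intervals)
    if (length(iv) != 2L || iv[1] >= iv[2])
      stop("obliteration intervals must be c(z_lo, z_hi) with z_lo < z_hi")
  # cord + CSF must fit inside the grid for every z
  ext <- (cfg$grid_shape[1:2] - 1) * cfg$voxel_spacing[1:2]
  reach <- max(cfg$radius_mm) + cfg$csf_thickness + abs(cfg$amplitude)
  if (any(reach > ext / 2 - max(cfg$voxel_spacing[1:2])))
    stop(sprintf(paste0("cord exits the grid: radius + CSF + deflection ",
                        "reach %.1f mm but the half-extent is only %.1f mm"),
                 reach, min(ext) / 2))
  invisible(cfg)
}

# evaluate the analytic centre line at world z (vectorized); returns n x 3
phantom_centerline <- function(cfg, zw) {
  cx <- (cfg$grid_shape[1] - 1) * cfg$voxel_spacing[1] / 2
  cy <- (cfg$grid_shape[2] - 1) * cfg$voxel_spacing[2] / 2
  phase <- 2 * pi * zw / cfg$wavelength
  x <- cx + cfg$amplitude * sin(phase)
  y <- if (cfg$helical) cy + cfg$amplitude * (cos(phase) - 1) else rep(cy, length(zw))
  cbind(x = x, y = y, z = zw)
}

# piecewise-linear cord radius at world z (vectorized)
phantom_radius <- function(cfg, zw) {
  zmax <- (cfg$grid_shape[3] - 1) * cfg$voxel_spacing[3]
  stats::approx(cfg$radius_z * zmax, cfg$radius_mm, xout = zw, rule = 2)$y
}

# evaluate code with a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cord phantom with analytic ground truth
#'
#' The truth mask is exactly the set of voxels whose centre lies within the
#' local cord radius of the analytic centre line (distance measured to the
#' curve, i.e. in the plane orthogonal to it); a CSF ring of configured
#' thickness surrounds the cord except in obliteration intervals.  Six
#' left/right pairs of rootlet markers tagged C3--C8 are placed on the cord
#' surface at increasing arc lengths.
#'
#' @param cfg a [phantom_config].
#' @return A `phantom_case`: list with `volume` ([cord_volume]),
#'   `truth_mask` ([cord_mask]), `truth_centerline` (one world point per
#'   axial slice), `markers` (data frame with `label`, `side`, `x`, `y`,
#'   `z`), the CSF-ring voxel bookkeeping used by [degrade()], and the
#'   config echo.
#' @export
generate_phantom <- function(cfg) {
  validate_phantom_config(cfg)
  dims <- cfg$grid_shape; sp <- cfg$voxel_spacing
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  xw <- (seq_len(nx) - 1) * sp[1]
  yw <- (seq_len(ny) - 1) * sp[2]
  zw <- (seq_len(nz) - 1) * sp[3]
  ints <- cfg$intensities
  vol <- array(ints[["tissue"]], dims)
  mask <- array(0L, dims)
  ring_idx <- integer(0); ring_z <- numeric(0)

  # dense centre-line samples for distance-to-curve queries
  hs <- 0.1
  zs <- seq(0, zw[nz], by = hs)
  cl <- phantom_centerline(cfg, zs)
  slope <- 2 * pi * cfg$amplitude / cfg$wavelength
  tilt <- sqrt(1 + slope^2)
  rmax_out <- max(cfg$radius_mm) + cfg$csf_thickness

  xg <- matrix(xw, nx, ny)
  yg <- matrix(yw, nx, ny, byrow = TRUE)
  for (k in seq_len(nz)) {
    c0 <- phantom_centerline(cfg, zw[k])
    d2d <- sqrt((xg - c0[1])^2 + (yg - c0[2])^2)
    cand <- which(d2d <= rmax_out * tilt + 1)
    if (!length(cand)) next
    win <- which(abs(zs - zw[k]) <= rmax_out * 1.5 + 0.5)
    px <- xg[cand]; py <- yg[cand]
    # candidate-by-sample squared distances to the curve
    dx <- outer(px, cl[win, 1], `-`)
    dy <- outer(py, cl[win, 2], `-`)
    dz2 <- (zw[k] - cl[win, 3])^2
    d2 <- dx * dx + dy * dy + rep(dz2, each = length(cand))
    jmin <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_along(cand), jmin)])
    rad <- phantom_radius(cfg, cl[win, 3][jmin])
    lin <- cand + (k - 1L) * nx * ny
    inside <- dmin <= rad
    ring <- !inside & dmin <= rad + cfg$csf_thickness
    mask[lin[inside]] <- 1L
    vol[lin[inside]] <- ints[["cord"]]
    obliterated <- in_intervals(zw[k], cfg$obliteration_intervals)
    vol[lin[ring]] <- if (obliterated) ints[["tissue"]] else ints[["csf"]]
    ring_idx <- c(ring_idx, lin[ring])
    ring_z <- c(ring_z, rep(zw[k], sum(ring)))
  }
  if (!any(mask == 1L)) stop("phantom truth mask is empty")

  centerline <- phantom_centerline(cfg, zw)
  markers <- phantom_markers(cfg)
  if (cfg$rootlet_artifact_count > 0L)
    vol <- paint_rootlet_streaks(vol, cfg, markers,
                                 cfg$rootlet_artifact_count,
                                 cfg$rootlet_artifact_radius)
  if (cfg$edge_softening_mm > 0)
    vol <- gaussian_blur3(vol, cfg$edge_softening_mm / sp)
  if (cfg$noise_sd > 0)
    vol <- vol + with_seed(cfg$seed,
                           array(stats::rnorm(length(vol), 0, cfg$noise_sd),
                                 dims))
  structure(list(volume = cord_volume(vol, sp),
                 truth_mask = cord_mask(mask, sp),
                 truth_centerline = centerline,
                 markers = markers,
                 csf_ring = list(index = ring_idx, z = ring_z),
                 config = cfg),
            class = "phantom_case")
}

in_intervals <- function(z, intervals) {
  for (iv in intervals) if (z >= iv[1] && z <= iv[2]) return(TRUE)
  FALSE
}

# 6 left/right marker pairs (C3..C8) on the cord surface, ordered in z
phantom_markers <- function(cfg) {
  zmax <- (cfg$grid_shape[3] - 1) * cfg$voxel_spacing[3]
  zf <- seq(0.12, 0.92, length.out = 6)
  labels <- paste0("C", 3:8)
  out <- NULL
  for (i in seq_along(zf)) {
    zc <- zf[i] * zmax
    p <- phantom_centerline(cfg, zc)
    r <- phantom_radius(cfg, zc)
    for (side in c(-1, 1)) {
      out <- rbind(out, data.frame(label = labels[i],
                                   side = if (side < 0) "L" else "R",
                                   x = p[1], y = p[2] + side * (r + 0.2),
                                   z = p[3]))
    }
  }
  rownames(out) <- NULL
  out
}

# dark thin cylinders crossing the CSF ring at marker positions
paint_rootlet_streaks <- function(vol, cfg, markers, count, radius) {
  sp <- cfg$voxel_spacing; dims <- dim(vol)
  dark <- 0.4 * cfg$intensities[["cord"]]
  use <- markers[seq_len(min(count, nrow(markers))), , drop = FALSE]
  for (i in seq_len(nrow(use))) {
    m <- use[i, ]
    c0 <- phantom_centerline(cfg, m$z)
    dir <- c(0, sign(m$y - c0[2]), 0)
    r_in <- phantom_radius(cfg, m$z)
    a <- c(c0[1], c0[2], c0[3]) + r_in * dir
    b <- a + (cfg$csf_thickness + 0.8) * dir
    lo <- pmax(floor(pmin(a, b) / sp) - ceiling(radius / sp), 0)
    hi <- pmin(ceiling(pmax(a, b) / sp) + ceiling(radius / sp), dims - 1)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    g <- expand.grid(i = ii, j = jj, k = kk)
    p <- cbind(g$i * sp[1], g$j * sp[2], g$k * sp[3])
    ab <- b - a
    tpar <- pmin(pmax(((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
                         (p[, 3] - a[3]) * ab[3]) / sum(ab^2), 0), 1)
    d <- sqrt((p[, 1] - a[1] - tpar * ab[1])^2 +
              (p[, 2] - a[2] - tpar * ab[2])^2 +
              (p[, 3] - a[3] - tpar * ab[3])^2)
    hit <- d <= radius
    if (any(hit)) {
      lin <- (g$i[hit] + 1L) + g$j[hit] * dims[1] +
        g$k[hit] * dims[1] * dims[2]
      vol[lin] <- dark
    }
  }
  vol
}

#' Degrade a phantom's intensities
#'
#' Adds Gaussian noise, obliterates the CSF ring over given z-ranges, and
#' paints dark rootlet-like streaks across the ring.  The truth mask and
#' centre line are untouched: degradation affects intensities only.
#'
#' @param case a `phantom_case` from [generate_phantom()].
#' @param noise_sd additional Gaussian noise sd (0 = none).
#' @param obliteration_intervals additional `c(z_lo, z_hi)` mm ranges whose
#'   CSF ring voxels are set to tissue intensity.
#' @param rootlet_artifacts number of dark streaks to add.
#' @param seed seed for the added noise (default derives from the config
#'   seed).
#' @return A `phantom_case` with modified intensities.
#' @export
degrade <- function(case, noise_sd = 0, obliteration_intervals = list(),
                    rootlet_artifacts = 0L, seed = case$config$seed + 5000L) {
  stopifnot(inherits(case, "phantom_case"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  cfg <- case$config
  vol <- case$volume$data
  for (iv in obliteration_intervals) {
    if (length(iv) != 2L || iv[1] >= iv[2])
      stop("obliteration intervals must be c(z_lo, z_hi) with z_lo < z_hi")
    sel <- case$csf_ring$z >= iv[1] & case$csf_ring$z <= iv[2]
    vol[case$csf_ring$index[sel]] <- cfg$intensities[["tissue"]]
  }
  if (rootlet_artifacts > 0L)
    vol <- paint_rootlet_streaks(vol, cfg, case$markers,
                                 rootlet_artifacts,
                                 cfg$rootlet_artifact_radius)
  if (noise_sd > 0)
    vol <- vol + with_seed(seed,
                           array(stats::rnorm(length(vol), 0, noise_sd),
                                 dim(vol)))
  out <- case
  out$volume <- cord_volume(vol, cfg$voxel_spacing)
  out
}

#' Write a phantom to disk
#'
#' Writes the volume and truth mask as NIfTI plus a JSON sidecar holding
#' the centre-line samples, rootlet markers, and a config echo.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$volume, file.path(dir, "volume.nii.gz"))
  write_mask(case$truth_mask, file.path(dir, "mask.nii.gz"))
  cfg <- case$config
  cfg$intensities <- as.list(cfg$intensities)
  jsonlite::write_json(list(centerline = case$truth_centerline,
                            markers = case$markers,
                            config = unclass(cfg)),
                       file.path(dir, "phantom.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
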