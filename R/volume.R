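#' Construct a volume object
#'
#' A `cord_volume` bundles a 3-D scalar array with its voxel spacing and a
#' voxel-index-to-world affine.  World coordinates are in millimetres; the
#' affine maps *0-based* voxel indices to world positions, following the
#' NIfTI convention, so the centre of voxel `[1, 1, 1]` (R indexing) sits at
#' `affine %*% c(0, 0, 0, 1)`.
#'
#' @param data 3-D numeric array of intensities (or gradient magnitudes).
#' @param spacing numeric length-3, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world matrix; default is a diagonal scaling
#'   by `spacing` with the origin at the first voxel centre.
#' @return An object of class `cord_volume`.
#' @export
cord_volume <- function(data, spacing = c(0.3906, 0.3906, 0.3),
                        affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array, got dimensionality ",
         length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine,
                 dtype = typeof(data)),
            class = "cord_volume")
}

#' @export
print.cord_volume <- function(x, ...) {
  cat(sprintf("<cord_volume> %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary mask volume
#'
#' A `cord_mask` is a `cord_volume` whose data are restricted to `{0, 1}`.
#' Values are stored as integers.
#'
#' @inheritParams cord_volume
#' @return An object of class `c("cord_mask", "cord_volume")`.
#' @export
cord_mask <- function(data, spacing = c(0.3906, 0.3906, 0.3), affine = NULL) {
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1)))
    stop("mask values must be 0/1; call read_mask() to normalize foreground")
  v <- cord_volume(array(as.integer(data), dim(data)), spacing, affine)
  class(v) <- c("cord_mask", class(v))
  v
}

# fractional 1-based voxel indices for an n x 3 matrix of world points
world_to_voxel <- function(vol, pts) {
  pts <- rbind(t(pts), 1)
  v <- solve(vol$affine, pts)
  t(v[1:3, , drop = FALSE]) + 1
}

# world coordinates of n x 3 (1-based, possibly fractional) voxel indices
voxel_to_world <- function(vol, idx) {
  idx <- rbind(t(idx) - 1, 1)
  w <- vol$affine %*% idx
  t(w[1:3, , drop = FALSE])
}

#' Read a 3-D volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [cord_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D volume, got a ", length(d), "-D image: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  spacing <- RNifti::pixdim(img)[1:3]
  cord_volume(array(as.numeric(img), d), spacing = abs(spacing), affine = aff)
}

#' Read a binary mask from a NIfTI file
#'
#' Any nonzero foreground label (e.g. `{0, 255}` exports) is normalized to
#' `{0, 1}`, with a warning when relabelling occurred.
#'
#' @inheritParams read_volume
#' @return A [cord_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  u <- sort(unique(as.vector(v$data)))
  if (!all(u %in% c(0, 1))) {
    if (any(u < 0)) stop("mask contains negative values: ", path)
    warning("mask values ", paste(u, collapse = "/"),
            " normalized to {0,1}: ", path)
    v$data <- array(as.integer(v$data > 0), dim(v$data))
  }
  cord_mask(v$data, spacing = v$spacing, affine = v$affine)
}

#' Write a volume or mask to a NIfTI file
#'
#' @param vol a [cord_volume] (or [cord_mask] for `write_mask`).
#' @param path destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "cord_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(vol, path) {
  stopifnot(inherits(vol, "cord_mask"))
  write_volume(vol, path)
}

#' Gradient-magnitude image
#'
#' Voxelwise Euclidean norm of the spatial intensity gradient, the image in
#' which the cord/CSF interface appears as a bright ring.  Differences are
#' central on interior voxels and one-sided at the borders, and each axis is
#' divided by its voxel spacing, so anisotropic voxels are handled in
#' physical (per-mm) units.
#'
#' @param vol a [cord_volume] with at least 2 voxels per axis.
#' @param axes axes to include; `1:3` (default) gives the full 3-D
#'   magnitude, `1:2` an in-plane (axial) gradient.
#' @return A [cord_volume] of nonnegative gradient magnitudes on the same
#'   grid.
#' @export
gradient_magnitude <- function(vol, axes = 1:3) {
  stopifnot(inherits(vol, "cord_volume"))
  d <- dim(vol$data)
  if (any(d < 2L)) stop("need >= 2 voxels per axis for a gradient")
  acc <- array(0, d)
  for (ax in axes) {
    g <- axis_gradient(vol$data, ax, vol$spacing[ax])
    acc <- acc + g * g
  }
  out <- vol
  out$data <- sqrt(acc)
  out$dtype <- "double"
  out
}

# reindex a 3-D array along one axis (used for shifts with edge clamping)
take_axis <- function(a, ax, idx) {
  args <- list(a, TRUE, TRUE, TRUE)
  args[ax + 1L] <- list(idx)
  do.call(`[`, c(args, list(drop = FALSE)))
}

# separable Gaussian blur with replicated borders; sigma_vox per axis
gaussian_blur3 <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-r:r, sd = s)
    w <- w / sum(w)
    n <- d[ax]
    out <- array(0, d)
    for (j in seq_along(w)) {
      o <- j - r - 1L
      out <- out + w[j] * take_axis(a, ax, pmin(pmax(1:n + o, 1L), n))
    }
    a <- out
  }
  a
}

# central differences interior, one-sided at the two faces, along axis ax
axis_gradient <- function(a, ax, h) {
  d <- dim(a)
  n <- d[ax]
  hi <- take_axis(a, ax, c(2:n, n))     # forward neighbour (clamped)
  lo <- take_axis(a, ax, c(1, 1:(n - 1)))
  # interior spans 2h; the clamped end differences span h
  den <- rep(2 * h, n)
  den[c(1, n)] <- h
  den_arr <- switch(ax,
                    array(rep(den, times = d[2] * d[3]), d),
                    array(rep(rep(den, each = d[1]), times = d[3]), d),
                    array(rep(den, each = d[1] * d[2]), d))
  (hi - lo) / den_arr
}

TEMPLATE_DB_VERSION <- 1L

#' Save / load a template database
#'
#' The template database holds every 70-sample radial gradient profile
#' extracted from one or more manually segmented (ground-truth) subjects,
#' with the cord/CSF edge index and provenance (subject, slice, angle) per
#' profile.  Persistence is R's native serialization with an explicit
#' format-version field checked on load.
#'
#' @param db a `template_db` (see [build_template_db()]).
#' @param path destination file.
#' @return `save_template_db`: `path`, invisibly.  `load_template_db`: the
#'   `template_db`.
#' @export
save_template_db <- function(db, path) {
  stopifnot(inherits(db, "template_db"))
  if (nrow(db$profiles) == 0L) stop("refusing to save an empty template db")
  payload <- unclass(db)
  payload$format_version <- TEMPLATE_DB_VERSION
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_template_db
#' @export
load_template_db <- function(path) {
  if (!file.exists(path)) stop("template db file not found: ", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("unreadable template db (",
                                               conditionMessage(e), "): ",
                                               path))
  ver <- payload$format_version
  if (is.null(ver) || !identical(as.integer(ver), TEMPLATE_DB_VERSION))
    stop("template db format version mismatch: found ",
         if (is.null(ver)) "<none>" else ver,
         ", expected ", TEMPLATE_DB_VERSION)
  payload$format_version <- NULL
  structure(payload, class = "template_db")
}
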