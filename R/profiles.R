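#' The radial direction set
#'
#' Radial profiles are taken in two-degree increments, 179 directions per
#' axial slice: `0, 2, ..., 356` degrees.
#'
#' @return Numeric vector of 179 angles in degrees.
#' @export
slice_angles <- function() seq(0, 356, by = 2)

N_RADIAL_SAMPLES <- 70L
RADIAL_STEP_MM <- 0.1

# Core radial walk.  From `center` (world mm) along unit `direction`, step
# in 0.1 mm increments; each step is assigned its nearest voxel, and a
# voxel's gradient value is appended the first time that voxel is
# encountered, until 70 voxels are collected.  Steps outside the grid
# contribute value 0 with their (out-of-range) voxel index kept as a
# placeholder.  Returns values, the voxel indices visited, and the walked
# distance (mm) at which each voxel was first met.
radial_walk <- function(vol, center, direction, n_voxels = N_RADIAL_SAMPLES,
                        step = RADIAL_STEP_MM) {
  dims <- dim(vol$data)
  # enough steps that even a diagonal walk crosses n_voxels distinct voxels
  n_steps <- ceiling(n_voxels * sqrt(sum(vol$spacing^2)) / step) + 20L
  kk <- 0:n_steps
  pos <- cbind(center[1] + kk * step * direction[1],
               center[2] + kk * step * direction[2],
               center[3] + kk * step * direction[3])
  vox <- round(world_to_voxel(vol, pos))
  key <- (vox[, 1] + 512) + (vox[, 2] + 512) * 4096 +
    (vox[, 3] + 512) * 4096^2
  first <- which(!duplicated(key))
  if (length(first) < n_voxels)
    stop("radial walk exhausted before collecting ", n_voxels, " voxels")
  first <- first[seq_len(n_voxels)]
  v <- vox[first, , drop = FALSE]
  inside <- v[, 1] >= 1 & v[, 1] <= dims[1] &
            v[, 2] >= 1 & v[, 2] <= dims[2] &
            v[, 3] >= 1 & v[, 3] <= dims[3]
  vals <- numeric(n_voxels)
  if (any(inside)) {
    lin <- v[inside, 1] + (v[inside, 2] - 1) * dims[1] +
      (v[inside, 3] - 1) * dims[1] * dims[2]
    vals[inside] <- vol$data[lin]
  }
  list(values = vals, voxel = v, inside = inside,
       dist = (first - 1) * step)
}

#' Extract one 70-sample radial gradient profile
#'
#' @param grad gradient-magnitude [cord_volume].
#' @param center world-mm point on the cord centre line (must lie inside
#'   the grid).
#' @param direction unit 3-vector orthogonal to the local centre-line
#'   tangent.
#' @param mask optional [cord_mask]; when given, the cord/CSF `edge_index`
#'   (0-based position of the last in-mask voxel of the contiguous run from
#'   the centre, bridging single-voxel holes) is recorded, as for template
#'   profiles.
#' @return A `radial_profile`: list with `values` (70 nonnegative gradient
#'   samples, zero beyond the image border), `voxel` (70 x 3 visited voxel
#'   indices), `dist` (walked mm at each sample), and `edge_index` (0-based,
#'   or `NULL` without a mask).
#' @export
extract_profile <- function(grad, center, direction, mask = NULL) {
  ci <- world_to_voxel(grad, matrix(center, 1))
  dims <- dim(grad$data)
  if (any(ci < 0.5) || any(ci > dims + 0.5))
    stop("profile center lies outside the volume grid")
  w <- radial_walk(grad, as.numeric(center), as.numeric(direction))
  edge <- NULL
  if (!is.null(mask)) {
    ins <- logical(N_RADIAL_SAMPLES)
    ok <- w$inside
    if (any(ok)) {
      v <- w$voxel[ok, , drop = FALSE]
      lin <- v[, 1] + (v[, 2] - 1) * dims[1] + (v[, 3] - 1) * dims[1] * dims[2]
      ins[ok] <- mask$data[lin] > 0
    }
    edge <- edge_from_inside(ins)
  }
  structure(list(values = w$values, voxel = w$voxel, dist = w$dist,
                 edge_index = edge),
            class = "radial_profile")
}

# last in-mask voxel of the run starting at the centre, bridging holes of
# at most one voxel; 0-based index, or NA if the centre is not in the mask
edge_from_inside <- function(ins) {
  if (!ins[1]) return(NA_integer_)
  r <- rle(ins)
  ends <- cumsum(r$lengths)
  edge <- r$lengths[1]           # 1-based end of the first TRUE run
  i <- 2L
  while (i + 1L <= length(r$lengths) &&
         !r$values[i] && r$lengths[i] <= 1L && r$values[i + 1L]) {
    edge <- ends[i + 1L]
    i <- i + 2L
  }
  as.integer(edge - 1L)
}

#' Build a template database from a manually segmented volume
#'
#' For every axial slice carrying mask voxels, the slice centroid of the
#' manual segmentation is taken as the cord centre and 179 radial gradient
#' profiles are extracted in the axial plane, each carrying the edge index
#' where the manual segmentation ends.  The collection over all slices (and
#' possibly several subjects, see [merge_template_dbs()]) is the template
#' database used to segment new volumes.
#'
#' @param grad gradient-magnitude [cord_volume].
#' @param manual_mask the manual segmentation as a [cord_mask] on the same
#'   grid.
#' @param subject_id provenance label for this subject.
#' @param angles radial directions in degrees (default [slice_angles()]).
#' @return A `template_db`: profile matrix (rows = radials, 70 columns),
#'   parallel `edge_index`, `slice_index`, `angle_deg` and `subject_id`
#'   vectors, and a per-subject manifest.
#' @export
build_template_db <- function(grad, manual_mask, subject_id = "subject1",
                              angles = slice_angles()) {
  stopifnot(inherits(manual_mask, "cord_mask"))
  if (!all(dim(grad$data) == dim(manual_mask$data)))
    stop("gradient volume and mask are on different grids")
  dims <- dim(grad$data)
  counts <- apply(manual_mask$data, 3, sum)
  slices <- which(counts > 0)
  if (!length(slices)) stop("mask is empty")
  rad <- angles * pi / 180
  n_ang <- length(angles)
  prof <- matrix(0, length(slices) * n_ang, N_RADIAL_SAMPLES)
  edge <- integer(nrow(prof)); sl <- integer(nrow(prof))
  ang <- numeric(nrow(prof))
  row <- 0L
  kept <- 0L
  for (k in slices) {
    if (counts[k] < 3) {
      warning("slice ", k, " has a degenerate (<3 voxel) cross-section; skipped")
      next
    }
    idx <- which(manual_mask$data[, , k] > 0, arr.ind = TRUE)
    centroid <- voxel_to_world(grad, cbind(colMeans(idx)[1], colMeans(idx)[2], k))
    for (a in seq_len(n_ang)) {
      dir <- c(cos(rad[a]), sin(rad[a]), 0)
      p <- extract_profile(grad, centroid, dir, mask = manual_mask)
      row <- row + 1L
      prof[row, ] <- p$values
      edge[row] <- p$edge_index
      sl[row] <- k
      ang[row] <- angles[a]
    }
    kept <- kept + 1L
  }
  if (row == 0L) stop("no usable slices in the mask")
  prof <- prof[seq_len(row), , drop = FALSE]
  structure(list(profiles = prof,
                 edge_index = edge[seq_len(row)],
                 slice_index = sl[seq_len(row)],
                 angle_deg = ang[seq_len(row)],
                 subject_id = rep(subject_id, row),
                 manifest = data.frame(subject = subject_id,
                                       n_slices = kept, n_profiles = row),
                 n_samples = N_RADIAL_SAMPLES),
            class = "template_db")
}

#' Merge template databases from several ground-truth subjects
#'
#' @param ... `template_db` objects.
#' @return A combined `template_db` (profiles stacked in argument order).
#' @export
merge_template_dbs <- function(...) {
  dbs <- list(...)
  stopifnot(length(dbs) >= 1L, all(vapply(dbs, inherits, TRUE, "template_db")))
  structure(list(profiles = do.call(rbind, lapply(dbs, `[[`, "profiles")),
                 edge_index = unlist(lapply(dbs, `[[`, "edge_index")),
                 slice_index = unlist(lapply(dbs, `[[`, "slice_index")),
                 angle_deg = unlist(lapply(dbs, `[[`, "angle_deg")),
                 subject_id = unlist(lapply(dbs, `[[`, "subject_id")),
                 manifest = do.call(rbind, lapply(dbs, `[[`, "manifest")),
                 n_samples = N_RADIAL_SAMPLES),
            class = "template_db")
}

#' @export
print.template_db <- function(x, ...) {
  cat(sprintf("<template_db> %d profiles x %d samples from %d subject(s)\n",
              nrow(x$profiles), x$n_samples, nrow(x$manifest)))
  invisible(x)
}

#' Extract test arrays along a fitted centre line
#'
#' Takes `n_slices` centres evenly spaced in arc length from `z = 0` (the
#' first marking) to the end of the spline; at each centre, 179 radial
#' profiles are extracted in the plane orthogonal to the local tangent.
#' Test profiles carry no edge index.
#'
#' @param grad gradient-magnitude [cord_volume].
#' @param spline a [cord_spline][fit_spline] fitted on this volume.
#' @param n_slices number of arc-length stations (default 100, i.e.
#'   100 x 179 = 17,900 test arrays).
#' @param angles radial directions in degrees.
#' @return A `test_arrays` object: `values` and `dist` matrices
#'   (`n_slices * length(angles)` rows, 70 columns), per-row `slice` and
#'   `angle_deg`, per-station arc positions `z_mm`, centres, and frames.
#' @export
extract_test_arrays <- function(grad, spline, n_slices = 100,
                                angles = slice_angles()) {
  zt <- seq(0, spline$total_length, length.out = n_slices)
  tt <- arc_to_t(spline, zt)
  rad <- angles * pi / 180
  n_ang <- length(angles)
  dims <- dim(grad$data)
  vals <- matrix(0, n_slices * n_ang, N_RADIAL_SAMPLES)
  dists <- matrix(0, n_slices * n_ang, N_RADIAL_SAMPLES)
  centers <- matrix(0, n_slices, 3)
  row <- 0L
  for (s in seq_len(n_slices)) {
    center <- as.numeric(eval_spline(spline, tt[s]))
    ci <- world_to_voxel(grad, matrix(center, 1))
    if (any(ci < 0.5) || any(ci > dims + 0.5))
      stop(sprintf("spline exits the volume at z = %.2f mm", zt[s]))
    centers[s, ] <- center
    fr <- spline_frame(spline, tt[s])
    for (a in seq_len(n_ang)) {
      dir <- cos(rad[a]) * fr$e1 + sin(rad[a]) * fr$e2
      w <- radial_walk(grad, center, dir)
      row <- row + 1L
      vals[row, ] <- w$values
      dists[row, ] <- w$dist
    }
  }
  structure(list(values = vals, dist = dists,
                 slice = rep(seq_len(n_slices), each = n_ang),
                 angle_deg = rep(angles, times = n_slices),
                 z_mm = zt, centers = centers),
            class = "test_arrays")
}
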