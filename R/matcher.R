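#' Normalized cross-correlation between two profiles
#'
#' Population-normalized (1/n) Pearson similarity of two equal-length
#' arrays: mean-centred, sigma-normalized dot product in `[-1, 1]`,
#' invariant to positive affine intensity rescaling of either array.  A
#' constant array has zero sigma; its similarity is defined as 0 and
#' flagged (such profiles are excluded from matching).
#'
#' @param f,t numeric vectors of equal length.
#' @return Similarity in `[-1, 1]`; attribute `"degenerate"` is `TRUE` when
#'   either array was constant.
#' @export
ncc <- function(f, t) {
  if (length(f) != length(t)) stop("profiles must have equal length")
  n <- length(f)
  fc <- f - mean(f); tc <- t - mean(t)
  sf <- sqrt(mean(fc^2)); st <- sqrt(mean(tc^2))
  if (sf == 0 || st == 0)
    return(structure(0, degenerate = TRUE))
  structure(sum(fc * tc) / (n * sf * st), degenerate = FALSE)
}

# row-normalize a profile matrix so that NCC = Un %*% t(Vn); constant rows
# become zero rows (NCC 0 with everything) and are reported
ncc_normalize_rows <- function(M) {
  ctr <- M - rowMeans(M)
  s <- sqrt(rowMeans(ctr^2))
  degen <- s < .Machine$double.eps
  s[degen] <- 1
  list(mat = ctr / (s * sqrt(ncol(M))), degenerate = degen)
}

#' Match one test profile against the template database
#'
#' The schedule starts at threshold 1.00 and decrements by 200 basis
#' points (0.02) until at least `n_target` templates reach the threshold;
#' if more qualify, the top `n_target` by NCC are kept (ties broken by
#' database insertion order).  If the floor is reached without `n_target`
#' matches, the top `n_target` by raw NCC are used and the result is
#' flagged as a fallback.
#'
#' @param test a `radial_profile`, or a plain numeric vector of 70 gradient
#'   samples.
#' @param db a `template_db`.
#' @param n_target number of matching templates sought (default 50).
#' @param step threshold decrement (default 0.02).
#' @param floor lowest threshold visited before falling back (default 0.30).
#' @return A `match_result`: `template_idx`, their `ncc` values, the
#'   `threshold` reached, a `fallback` flag, and the `inferred_edge`
#'   (arithmetic mean of the matched templates' edge indices, fractional,
#'   0-based).
#' @export
find_matches <- function(test, db, n_target = 50, step = 0.02, floor = 0.30) {
  stopifnot(inherits(db, "template_db"))
  v <- if (inherits(test, "radial_profile")) test$values else as.numeric(test)
  norm <- ncc_normalize_rows(db$profiles)
  tn <- ncc_normalize_rows(matrix(v, 1))
  scores <- as.numeric(norm$mat %*% t(tn$mat))
  res <- match_schedule(scores, n_target, step, floor)
  res$inferred_edge <- mean(db$edge_index[res$template_idx])
  structure(res, class = "match_result")
}

# threshold schedule on a precomputed NCC score vector
match_schedule <- function(scores, n_target = 50, step = 0.02, floor = 0.30,
                           warn_small = TRUE) {
  n <- length(scores)
  k <- n_target
  if (n < n_target) {
    if (warn_small)
      warning("template database holds only ", n, " profiles; using all")
    k <- n
  }
  eps <- 1e-9
  vk <- if (k == n) min(scores) else -sort(-scores, partial = k)[k]
  sched <- seq(1, floor, by = -step)
  ok <- sched <= vk + eps
  if (any(ok)) {
    threshold <- sched[which(ok)[1]]
    cand <- which(scores >= threshold - eps)
    if (length(cand) > k) cand <- cand[order(-scores[cand])[seq_len(k)]]
    fallback <- FALSE
  } else {
    cand <- order(-scores)[seq_len(k)]
    threshold <- NA_real_
    fallback <- TRUE
  }
  list(template_idx = cand, ncc = scores[cand], threshold = threshold,
       fallback = fallback)
}

#' Infer the edge position from a match result
#'
#' @param match a `match_result` with the matched templates' edge indices
#'   available, or a numeric vector of edge indices.
#' @param db the `template_db` the match was made against (needed when
#'   `match` is a `match_result`).
#' @return Fractional 0-based edge index: the arithmetic mean of the
#'   matched templates' edge indices.
#' @export
infer_edge <- function(match, db = NULL) {
  if (inherits(match, "match_result")) {
    if (!is.null(match$inferred_edge)) return(match$inferred_edge)
    stopifnot(!is.null(db))
    return(mean(db$edge_index[match$template_idx]))
  }
  mean(as.numeric(match))
}

# fractional 0-based edge index -> walked mm, using the test radial's own
# distance table; the edge sits at the boundary of its voxel, i.e. halfway
# between the first-encounter distances of the edge voxel and the next
edge_index_to_mm <- function(edge, dist) {
  n <- length(dist)
  mid <- c((dist[-n] + dist[-1]) / 2, dist[n] + (dist[n] - dist[n - 1]) / 2)
  stats::approx(0:(n - 1), mid, xout = pmin(pmax(edge, 0), n - 1), rule = 2)$y
}

#' Interpolate a sparse edge field to all axial slices
#'
#' Matching is run on (typically) 100 stations down the cord; the edge
#' information for the remaining axial slices is linearly interpolated per
#' angle in z.  No extrapolation occurs beyond the first and last matched
#' station.
#'
#' @param field a sparse `edge_field` (see [segment_cord()]) whose rows sit
#'   at fractional axial-slice positions.
#' @return A dense `edge_field` with one row per integer axial slice
#'   between the first and last matched station; cells carry a
#'   `matched`/`interpolated` provenance flag.
#' @export
interpolate_edge_field <- function(field) {
  stopifnot(inherits(field, "edge_field"))
  pos <- field$slice_pos
  if (length(unique(round(pos * 1e6))) < 2L)
    stop("need at least 2 matched slices to interpolate")
  out_slices <- seq(ceiling(min(pos) - 1e-9), floor(max(pos) + 1e-9))
  n_ang <- ncol(field$index)
  idx <- matrix(0, length(out_slices), n_ang)
  mm <- matrix(0, length(out_slices), n_ang)
  for (a in seq_len(n_ang)) {
    idx[, a] <- stats::approx(pos, field$index[, a], xout = out_slices,
                              ties = mean)$y
    mm[, a] <- stats::approx(pos, field$mm[, a], xout = out_slices,
                             ties = mean)$y
  }
  status <- matrix("interpolated", length(out_slices), n_ang)
  matched_rows <- out_slices %in% round(pos)
  status[matched_rows, ] <- "matched"
  structure(list(slice_pos = out_slices, angle_deg = field$angle_deg,
                 index = idx, mm = mm, status = status,
                 fallback = NULL),
            class = "edge_field")
}

# sliding median with circular padding
median_filter_circular <- function(x, k) {
  hw <- (k - 1L) / 2L
  n <- length(x)
  xp <- c(x[(n - hw + 1L):n], x, x[1:hw])
  apply(embed(xp, k), 1, stats::median)
}

# sliding median with reflect padding
median_filter_reflect <- function(x, k) {
  hw <- (k - 1L) / 2L
  n <- length(x)
  if (n == 1L) return(x)
  pre <- x[pmin(hw:1 + 1L, n)]
  post <- x[pmax(n - (1:hw), 1L)]
  apply(embed(c(pre, x, post), k), 1, stats::median)
}

#' Median-smooth an edge field
#'
#' Applies a cascade of one-dimensional median filters to the located edge
#' distances: for each kernel size in order, first around the axial plane
#' (over theta, with circular wrap) and then along the cord (over z at
#' constant theta, with reflect padding).  Intended to remove outlier edges
#' in regions of reduced or obliterated CSF.
#'
#' @param field a dense (interpolated) `edge_field`.
#' @param kernels odd kernel sizes applied in cascade (default `c(5, 7, 9)`).
#' @return The smoothed `edge_field`; cells are flagged `smoothed`.
#' @export
smooth_edge_field <- function(field, kernels = c(5, 7, 9)) {
  stopifnot(inherits(field, "edge_field"))
  if (any(kernels %% 2 == 0)) stop("median kernel sizes must be odd")
  idx <- field$index; mm <- field$mm
  for (k in kernels) {
    for (r in seq_len(nrow(idx))) {
      idx[r, ] <- median_filter_circular(idx[r, ], k)
      mm[r, ] <- median_filter_circular(mm[r, ], k)
    }
    if (nrow(idx) >= 2L) {
      for (a in seq_len(ncol(idx))) {
        idx[, a] <- median_filter_reflect(idx[, a], k)
        mm[, a] <- median_filter_reflect(mm[, a], k)
      }
    }
  }
  out <- field
  out$index <- pmin(pmax(idx, 0), N_RADIAL_SAMPLES - 1)
  out$mm <- pmax(mm, 0)
  out$status[] <- "smoothed"
  out
}

#' Rasterize one axial slice from polar edge distances
#'
#' A voxel centre is inside the slice mask iff its in-plane polar radius
#' about the slice centre does not exceed the edge distance linearly
#' interpolated between the two adjacent radial angles — a star-convex
#' region about the centre.
#'
#' @param center world-mm cord centre of this slice.
#' @param angles_deg radial angles (degrees, measured from the world +x
#'   axis in the axial plane).
#' @param edge_mm edge distance in mm for each angle.
#' @param dims in-plane voxel counts `c(nx, ny)`.
#' @param spacing in-plane spacing `c(sx, sy)` in mm.
#' @return Logical `nx x ny` matrix.
#' @export
rasterize_slice <- function(center, angles_deg, edge_mm, dims, spacing) {
  out <- matrix(FALSE, dims[1], dims[2])
  emax <- max(edge_mm)
  if (emax <= 0) return(out)
  i_lo <- max(1L, floor((center[1] - emax) / spacing[1]) + 1L)
  i_hi <- min(dims[1], ceiling((center[1] + emax) / spacing[1]) + 1L)
  j_lo <- max(1L, floor((center[2] - emax) / spacing[2]) + 1L)
  j_hi <- min(dims[2], ceiling((center[2] + emax) / spacing[2]) + 1L)
  if (i_lo > i_hi || j_lo > j_hi) return(out)
  ii <- i_lo:i_hi; jj <- j_lo:j_hi
  dx <- (ii - 1) * spacing[1] - center[1]
  dy <- (jj - 1) * spacing[2] - center[2]
  DX <- matrix(dx, length(ii), length(jj))
  DY <- matrix(dy, length(ii), length(jj), byrow = TRUE)
  r <- sqrt(DX^2 + DY^2)
  th <- (atan2(DY, DX) * 180 / pi) %% 360
  # periodic linear interpolation of the edge function over theta
  xa <- c(angles_deg, 360)
  ya <- c(edge_mm, edge_mm[1])
  e <- stats::approx(xa, ya, xout = as.vector(th), rule = 2)$y
  out[ii, jj] <- r <= matrix(e, length(ii), length(jj))
  out
}

# in-plane connected-component labelling (4-connectivity) of one slice;
# returns the linear indices of the largest component
largest_component <- function(slice_mat) {
  idx <- which(slice_mat)
  if (length(idx) == 0L) return(idx)
  nx <- nrow(slice_mat)
  lab <- integer(length(slice_mat))
  lab[idx] <- -1L               # foreground, unlabelled
  best <- integer(0)
  cur <- 0L
  for (s in idx) {
    if (lab[s] != -1L) next
    cur <- cur + 1L
    stack <- s
    comp <- integer(0)
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, p)
      i <- (p - 1L) %% nx + 1L
      nb <- c(if (i > 1L) p - 1L, if (i < nx) p + 1L,
              p - nx, p + nx)
      nb <- nb[nb >= 1L & nb <= length(slice_mat)]
      nb <- nb[lab[nb] == -1L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
    if (length(comp) > length(best)) best <- comp
  }
  best
}

#' Refine the centre line from a segmentation mask
#'
#' Computes the centroid of every segmented axial plane, resamples the
#' centroid path to exactly `n_control` control points evenly spaced in z,
#' and fits a new spline through them.  Fragmented slices use the largest
#' connected component's centroid (with a warning).
#'
#' @param mask a [cord_mask] nonempty on at least 4 axial slices.
#' @param n_control number of refined control points (default 500).
#' @param d0 reference direction for the refined cylindrical frame.
#' @return A [cord_spline][fit_spline] with `n_control` control points.
#' @export
recenter <- function(mask, n_control = 500, d0 = c(1, 0, 0)) {
  stopifnot(inherits(mask, "cord_mask"))
  counts <- apply(mask$data, 3, sum)
  slices <- which(counts > 0)
  if (length(slices) < 4L) stop("mask must be nonempty on >= 4 axial slices")
  cent <- matrix(0, length(slices), 3)
  fragmented <- 0L
  for (s in seq_along(slices)) {
    k <- slices[s]
    sl <- mask$data[, , k] > 0
    comp <- largest_component(sl)
    if (length(comp) < sum(sl)) fragmented <- fragmented + 1L
    ij <- arrayInd(comp, dim(sl))
    cent[s, ] <- colMeans(voxel_to_world(mask, cbind(ij[, 1], ij[, 2], k)))
  }
  if (fragmented > 0L)
    warning(fragmented, " fragmented slice(s); used the largest component")
  zc <- cent[, 3]
  o <- order(zc)
  cent <- cent[o, , drop = FALSE]; zc <- zc[o]
  z_new <- seq(zc[1], zc[length(zc)], length.out = n_control)
  ctrl <- cbind(stats::approx(zc, cent[, 1], xout = z_new)$y,
                stats::approx(zc, cent[, 2], xout = z_new)$y,
                z_new)
  new_spline(ctrl, d0 = d0, samples_per_segment = 8L)
}

# rasterize a dense edge field slice by slice into a mask on the volume's
# grid; the slice centre is the spline point at that slice's world z
rasterize_field <- function(volume, spline, field) {
  dims <- dim(volume$data)
  mask_arr <- array(0L, dims)
  tab_z <- spline$table$points[, 3]
  for (r in seq_along(field$slice_pos)) {
    k <- field$slice_pos[r]
    if (k < 1 || k > dims[3]) next
    zw <- voxel_to_world(volume, cbind(1, 1, k))[3]
    tk <- stats::approx(tab_z, spline$table$t, xout = zw, rule = 2,
                        ties = mean)$y
    center <- as.numeric(eval_spline(spline, tk))
    sl <- rasterize_slice(center, field$angle_deg, field$mm[r, ],
                          dims[1:2], volume$spacing[1:2])
    mask_arr[, , k] <- as.integer(sl)
  }
  cord_mask(mask_arr, spacing = volume$spacing, affine = volume$affine)
}

#' Re-apply smoothing to an existing segmentation
#'
#' Applies the median smoothing cascade to a segmentation's edge field and
#' re-rasterizes, reusing the already-computed template matches — useful
#' for A/B comparison of the optional smoothing step.
#'
#' @param seg a `cord_segmentation` from [segment_cord()].
#' @param volume the volume that was segmented.
#' @param kernels smoothing kernel sizes.
#' @return A new `cord_segmentation` with the smoothed field, mask and
#'   refined spline.
#' @export
smooth_segmentation <- function(seg, volume, kernels = c(5, 7, 9)) {
  stopifnot(inherits(seg, "cord_segmentation"))
  field <- smooth_edge_field(seg$edge_field, kernels)
  mask <- rasterize_field(volume, seg$spline, field)
  out <- seg
  out$edge_field <- field
  out$mask <- mask
  out$refined_spline <- recenter(mask, n_control = 500)
  out$meta$params$smooth <- TRUE
  out$meta$params$kernels <- kernels
  out
}

#' Segment a volume by 1-D normalized template matching
#'
#' The full pipeline: fit the 20-control-point centre-line spline to the
#' manual markings, compute the gradient-magnitude image, extract
#' 179-radial test arrays at `n_slices` stations evenly spaced in arc
#' length, match each against the whole template database under the
#' 1.00-down-to-floor NCC threshold schedule, average the matched
#' templates' edge indices, interpolate the edge field to every axial
#' slice, optionally median-smooth it, rasterize each slice to a
#' star-convex region about the centre, and refine the centre line from
#' the per-slice centroids (500 control points).
#'
#' @param volume the [cord_volume] to segment.
#' @param markings n x 3 world-mm centre-line markings (first = the
#'   ponto-medullary-junction analogue, the arc-length origin).
#' @param db the `template_db` built from ground-truth subjects.
#' @param n_control initial spline control points (default 20).
#' @param n_slices matching stations (default 100).
#' @param n_matches templates sought per test array (default 50).
#' @param step threshold decrement (default 0.02).
#' @param floor threshold floor (default 0.30).
#' @param smooth apply the median smoothing cascade (default `FALSE`, the
#'   base case).
#' @param kernels smoothing kernel sizes (default `c(5, 7, 9)`).
#' @param gradient_axes `1:3` for the 3-D gradient magnitude (default) or
#'   `1:2` for in-plane.
#' @param d0 reference direction for theta = 0.
#' @return A `cord_segmentation`: the `mask`, the `refined_spline` (500
#'   control points), the initial `spline`, the dense `edge_field`, and run
#'   metadata (per-station thresholds, fallback count, parameter echo).
#' @export
segment_cord <- function(volume, markings, db,
                         n_control = 20, n_slices = 100, n_matches = 50,
                         step = 0.02, floor = 0.30,
                         smooth = FALSE, kernels = c(5, 7, 9),
                         gradient_axes = 1:3, d0 = c(1, 0, 0)) {
  stopifnot(inherits(volume, "cord_volume"), inherits(db, "template_db"))
  t0 <- proc.time()[["elapsed"]]
  spline <- fit_spline(markings, n_control = n_control, d0 = d0)
  grad <- gradient_magnitude(volume, axes = gradient_axes)
  tests <- extract_test_arrays(grad, spline, n_slices = n_slices)
  t_extract <- proc.time()[["elapsed"]]

  norm_db <- ncc_normalize_rows(db$profiles)
  norm_f <- ncc_normalize_rows(tests$values)
  n_ang <- length(unique(tests$angle_deg))
  edges <- matrix(0, n_slices, n_ang)
  edges_mm <- matrix(0, n_slices, n_ang)
  thresholds <- matrix(NA_real_, n_slices, n_ang)
  fallback <- matrix(FALSE, n_slices, n_ang)
  warned_small <- FALSE
  for (s in seq_len(n_slices)) {
    rows <- which(tests$slice == s)
    scores <- norm_db$mat %*% t(norm_f$mat[rows, , drop = FALSE])
    for (a in seq_len(n_ang)) {
      m <- match_schedule(scores[, a], n_matches, step, floor,
                          warn_small = !warned_small)
      if (nrow(db$profiles) < n_matches) warned_small <- TRUE
      e <- mean(db$edge_index[m$template_idx])
      edges[s, a] <- e
      edges_mm[s, a] <- edge_index_to_mm(e, tests$dist[rows[a], ])
      thresholds[s, a] <- m$threshold
      fallback[s, a] <- m$fallback
    }
  }
  t_match <- proc.time()[["elapsed"]]

  # station arc positions -> fractional axial slice indices
  slice_pos <- world_to_voxel(volume, tests$centers)[, 3]
  o <- order(slice_pos)
  sparse <- structure(list(slice_pos = slice_pos[o],
                           angle_deg = sort(unique(tests$angle_deg)),
                           index = edges[o, , drop = FALSE],
                           mm = edges_mm[o, , drop = FALSE],
                           status = matrix("matched", n_slices, n_ang),
                           fallback = fallback[o, , drop = FALSE]),
                      class = "edge_field")
  field <- interpolate_edge_field(sparse)
  if (smooth) field <- smooth_edge_field(field, kernels)

  mask <- rasterize_field(volume, spline, field)
  refined <- recenter(mask, n_control = 500, d0 = d0)
  t_end <- proc.time()[["elapsed"]]

  structure(list(mask = mask, refined_spline = refined, spline = spline,
                 edge_field = field,
                 meta = list(thresholds = thresholds, fallback = fallback,
                             n_fallback = sum(fallback),
                             params = list(n_control = n_control,
                                           n_slices = n_slices,
                                           n_matches = n_matches,
                                           step = step, floor = floor,
                                           smooth = smooth,
                                           kernels = kernels,
                                           gradient_axes = gradient_axes),
                             timing = c(extract = t_extract - t0,
                                        match = t_match - t_extract,
                                        raster = t_end - t_match))),
            class = "cord_segmentation")
}

#' @export
print.cord_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<cord_segmentation> %d voxels over %d slices; ",
                     "%d fallback cells; refined spline %d control points\n"),
              sum(x$mask$data), length(x$edge_field$slice_pos),
              x$meta$n_fallback, x$refined_spline$n))
  invisible(x)
}
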