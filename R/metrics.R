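#' Dice coefficient between two masks
#'
#' Volumetric overlap `2|A ^ B| / (|A| + |B|)` in `[0, 1]`.
#'
#' @param a,b [cord_mask] objects on the same grid.
#' @return Dice coefficient.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "cord_mask"), inherits(b, "cord_mask"))
  if (!all(dim(a$data) == dim(b$data)))
    stop("masks are on different grids")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) stop("Dice undefined: both masks are empty")
  2 * sum(a$data & b$data) / (na + nb)
}

# centre-line point of a spline at a given axial world z (assumes the curve
# is monotone in world z, as a cord centre line is)
spline_point_at_z <- function(sp, zw) {
  tz <- stats::approx(sp$table$points[, 3], sp$table$t, xout = zw,
                      ties = mean)$y
  eval_spline(sp, tz)
}

#' Mean centre-line distance between two splines
#'
#' The in-plane Euclidean distance between the two centre lines is
#' evaluated on each axial slice of the overlapping z-range and summed over
#' the `n - 1` slices after the origin slice, divided by `n - 1` — the
#' per-slice average distance, measuring the agreement of arc-distance
#' calculations.
#'
#' @param spline_a,spline_b [cord_spline][fit_spline] objects.
#' @param z_range optional `c(z_lo, z_hi)` world-mm interval; default is
#'   the overlap of the two splines' axial extents.
#' @param slice_spacing axial slice thickness in mm.
#' @return Mean distance in mm.
#' @export
mean_centerline_distance <- function(spline_a, spline_b, z_range = NULL,
                                     slice_spacing = 0.3) {
  za <- range(spline_a$table$points[, 3])
  zb <- range(spline_b$table$points[, 3])
  lo <- max(za[1], zb[1]); hi <- min(za[2], zb[2])
  if (!is.null(z_range)) {
    lo <- max(lo, min(z_range)); hi <- min(hi, max(z_range))
  }
  if (hi <= lo) stop("splines do not overlap in the requested z-range")
  zs <- seq(lo, hi, by = slice_spacing)
  if (length(zs) < 2L) stop("z-range spans fewer than 2 axial slices")
  pa <- spline_point_at_z(spline_a, zs)
  pb <- spline_point_at_z(spline_b, zs)
  d <- sqrt((pa[, 1] - pb[, 1])^2 + (pa[, 2] - pb[, 2])^2)
  sum(d[-1]) / (length(zs) - 1)
}

# world coordinates of the boundary voxels (6-connectivity surface) of a mask
mask_surface_points <- function(mask) {
  m <- mask$data > 0
  d <- dim(m)
  shift <- function(ax, by) {
    out <- array(FALSE, d)
    n <- d[ax]
    src <- if (by > 0) 1:(n - 1) else 2:n
    dst <- if (by > 0) 2:n else 1:(n - 1)
    ix <- function(which_ax, i) if (which_ax == ax) i else TRUE
    if (ax == 1) out[dst, , ] <- m[src, , ]
    if (ax == 2) out[, dst, ] <- m[, src, ]
    if (ax == 3) out[, , dst] <- m[, , src]
    out
  }
  interior <- m
  for (ax in 1:3) for (by in c(-1, 1))
    interior <- interior & shift(ax, by)
  idx <- which(m & !interior, arr.ind = TRUE)
  voxel_to_world(mask, idx)
}

# directed Hausdorff max-min distance between two point sets, chunked
directed_hausdorff <- function(P, Q, chunk = 512L) {
  worst <- 0
  q2 <- rowSums(Q^2)
  for (start in seq(1L, nrow(P), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(P))
    Pc <- P[idx, , drop = FALSE]
    d2 <- outer(rowSums(Pc^2), q2, `+`) - 2 * Pc %*% t(Q)
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(max(worst, 0))
}

#' Hausdorff distance between two segmentation surfaces
#'
#' `max(D(S1, S2), D(S2, S1))` where `D` is the maximum over one surface of
#' the distance to the nearest point of the other, computed on boundary
#' voxel centres in world mm.  Captures large outlier segmentation points.
#'
#' @inheritParams dice
#' @return Hausdorff distance in mm.
#' @export
hausdorff <- function(a, b) {
  stopifnot(inherits(a, "cord_mask"), inherits(b, "cord_mask"))
  if (!all(dim(a$data) == dim(b$data)))
    stop("masks are on different grids")
  if (sum(a$data) == 0 || sum(b$data) == 0)
    stop("Hausdorff undefined for an empty mask")
  P <- mask_surface_points(a)
  Q <- mask_surface_points(b)
  max(directed_hausdorff(P, Q), directed_hausdorff(Q, P))
}

#' Define a cord region from rootlet markers
#'
#' Projects the rostral and caudal marker points onto the shared spline
#' (nearest-point projection), yielding the arc-length interval that
#' demarcates the region (e.g. a C3--C8 cord segment bounded by nerve
#' rootlets).
#'
#' @param spline the shared [cord_spline][fit_spline].
#' @param rostral,caudal world-mm marker points.
#' @param label region label (e.g. `"C5"`).
#' @return A `region_spec`: `label` and the `z` interval `c(z_lo, z_hi)` in
#'   arc-length mm.
#' @export
region_from_markers <- function(spline, rostral, caudal, label = "") {
  z1 <- euclid_to_cyl(spline, rostral)[["z"]]
  z2 <- euclid_to_cyl(spline, caudal)[["z"]]
  if (z1 >= z2)
    stop("rostral marker projects caudal of the caudal marker")
  structure(list(label = label, z = c(z1, z2)), class = "region_spec")
}

#' Regional cross-sectional area
#'
#' `CSA = (segmented voxels whose projected z falls in the region) x voxel
#' volume / region arc length`.  Voxels are projected onto the shared
#' spline so centre-line disagreement does not enter the comparison.
#'
#' @param mask a [cord_mask].
#' @param spline the shared [cord_spline][fit_spline].
#' @param region a `region_spec` (or `c(z_lo, z_hi)` in arc-length mm).
#' @return Cross-sectional area in mm^2.
#' @export
regional_csa <- function(mask, spline, region) {
  z <- if (inherits(region, "region_spec")) region$z else as.numeric(region)
  len <- z[2] - z[1]
  if (len <= 0) stop("region has zero arc length")
  idx <- which(mask$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  pts <- voxel_to_world(mask, idx)
  proj <- project_to_spline(spline, pts)
  n_in <- sum(proj$z >= z[1] & proj$z < z[2])
  voxvol <- abs(det(mask$affine[1:3, 1:3]))
  n_in * voxvol / len
}

#' Absolute cross-sectional-area difference
#'
#' @param csa1,csa2 areas in mm^2.
#' @return `|csa2 - csa1|` in mm^2.
#' @export
csa_abs_diff <- function(csa1, csa2) abs(csa2 - csa1)

#' Aggregate validation metrics over a cohort
#'
#' For each cohort entry, computes Dice, mean centre-line distance and
#' Hausdorff distance between the two segmentations, and per-region CSAs
#' and absolute CSA differences on the shared spline.  Aggregates with
#' cohort mean, sample (n-1) standard deviation, and absolute min/max, the
#' way segmentation validation tables are reported.
#'
#' @param entries list of entries, each a list with `id`, masks `mask_a`
#'   and `mask_b`, splines `spline_a` and `spline_b` (MD is computed
#'   between them), `spline` (the shared spline for CSA; defaults to
#'   `spline_a`), and optionally `regions`, a named list of `region_spec`s.
#' @param slice_spacing axial slice thickness in mm for MD.
#' @return A `metric_report`: `per_pair` data frame, `csa` data frame (one
#'   row per entry x region), and `summary` data frame with mean, sd, min,
#'   max per metric.
#' @export
cohort_report <- function(entries, slice_spacing = 0.3) {
  per <- NULL; csa_rows <- NULL
  for (e in entries) {
    shared <- if (!is.null(e$spline)) e$spline else e$spline_a
    row <- data.frame(id = e$id,
                      dice = dice(e$mask_a, e$mask_b),
                      md = mean_centerline_distance(e$spline_a, e$spline_b,
                                                    slice_spacing = slice_spacing),
                      hd = hausdorff(e$mask_a, e$mask_b))
    per <- rbind(per, row)
    for (rn in names(e$regions)) {
      reg <- e$regions[[rn]]
      c1 <- regional_csa(e$mask_a, shared, reg)
      c2 <- regional_csa(e$mask_b, shared, reg)
      csa_rows <- rbind(csa_rows,
                        data.frame(id = e$id, region = rn, csa_a = c1,
                                   csa_b = c2,
                                   abs_diff = csa_abs_diff(c1, c2)))
    }
  }
  agg <- function(x) c(mean = mean(x), sd = stats::sd(x),
                       min = min(x), max = max(x))
  summary <- rbind(data.frame(metric = "dice", t(agg(per$dice))),
                   data.frame(metric = "md_mm", t(agg(per$md))),
                   data.frame(metric = "hd_mm", t(agg(per$hd))))
  structure(list(per_pair = per, csa = csa_rows, summary = summary),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> over", nrow(x$per_pair), "pair(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a metric report to CSV and JSON
#'
#' @param report a `metric_report`.
#' @param prefix path prefix; writes `<prefix>_pairs.csv`,
#'   `<prefix>_csa.csv`, `<prefix>_summary.csv` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_metric_report <- function(report, prefix) {
  utils::write.csv(report$per_pair, paste0(prefix, "_pairs.csv"),
                   row.names = FALSE)
  if (!is.null(report$csa))
    utils::write.csv(report$csa, paste0(prefix, "_csa.csv"),
                     row.names = FALSE)
  utils::write.csv(report$summary, paste0(prefix, "_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(report), paste0(prefix, ".json"),
                       digits = NA, dataframe = "rows")
  invisible(prefix)
}
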