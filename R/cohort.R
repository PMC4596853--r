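#' Phantom configurations for a leave-one-out cohort
#'
#' Builds `n` phantom configurations sharing one grid but differing in
#' centre-line curvature, cord radius scale and noise realization, the way
#' a small cohort of healthy subjects differs.  Subjects beyond
#' `first_obliterated - 1` additionally carry two z-ranges of obliterated
#' CSF, the failure mode the optional smoothing cascade targets.
#'
#' @param n cohort size.
#' @param grid_shape,voxel_spacing phantom grid (see [phantom_config()]).
#' @param seed base seed; subject `i` uses `seed * 100 + i`.
#' @param first_obliterated 1-based index of the first subject with
#'   obliterated-CSF intervals (`Inf` for none).
#' @return List of [phantom_config] objects.
#' @export
cohort_configs <- function(n = 6, grid_shape = c(128L, 128L, 100L),
                           voxel_spacing = c(0.3906, 0.3906, 0.3),
                           seed = 1L, first_obliterated = 5L) {
  zext <- (grid_shape[3] - 1) * voxel_spacing[3]
  # template subject sits mid-range (moderate curvature, radius scale 1);
  # the others spread from straight to strongly curved and +/- 4% in radius
  amp <- c(1.2, seq(0, 2.5, length.out = n - 1))
  rscale <- c(1, seq(0.96, 1.04, length.out = n - 1))
  lapply(seq_len(n), function(i) {
    obl <- if (i >= first_obliterated)
      list(c(0.30, 0.42) * zext, c(0.62, 0.72) * zext)
    else list()
    phantom_config(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                   amplitude = amp[i], wavelength = 80,
                   radius_mm = c(4.6, 5.0, 5.3, 4.4) * rscale[i],
                   obliteration_intervals = obl,
                   seed = seed * 100L + i)
  })
}

#' Spline through a phantom's analytic truth centre line
#'
#' @param case a `phantom_case`.
#' @param n_control control points subsampled from the truth centre line.
#' @return A [cord_spline][fit_spline] for use as the truth reference in
#'   centre-line distance and CSA calculations.
#' @export
truth_spline <- function(case, n_control = 50) {
  cl <- case$truth_centerline
  idx <- unique(round(seq(1, nrow(cl), length.out = min(n_control, nrow(cl)))))
  new_spline(cl[idx, , drop = FALSE], samples_per_segment = 20L)
}

#' Emulate manual centre-line markings on a phantom
#'
#' Returns the truth centre line plus smooth in-plane rater drift: a
#' rater's click error is spatially correlated, not white — it drifts
#' slowly along the cord (moving-average-filtered Gaussian noise).
#'
#' @param case a `phantom_case`.
#' @param sd_mm in-plane drift standard deviation in mm.
#' @param n number of markings returned.
#' @param seed seed for the drift realization.
#' @return `n x 3` matrix of world-mm markings, rostral to caudal.
#' @export
jitter_markings <- function(case, sd_mm = 0.3, n = 40, seed = 1L) {
  cl <- case$truth_centerline
  idx <- unique(round(seq(1, nrow(cl), length.out = n)))
  m <- cl[idx, , drop = FALSE]
  if (sd_mm > 0) {
    k <- 7L
    nr <- nrow(m)
    drift <- with_seed(seed, {
      raw <- matrix(stats::rnorm(2 * (nr + 2 * k), 0, sd_mm * sqrt(k)),
                    ncol = 2)
      sm <- apply(raw, 2, function(x)
        as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)))
      sm[(k + 1):(k + nr), , drop = FALSE]
    })
    m[, 1:2] <- m[, 1:2] + drift
  }
  m
}

#' Leave-one-out segmentation evaluation over a phantom cohort
#'
#' Mirrors the validation protocol of the method: the template database is
#' built from one subject's ground truth, every other subject is segmented
#' from jittered centre-line markings, and each segmentation is scored
#' against its analytic truth (Dice, mean centre-line distance against the
#' truth centre line, Hausdorff distance).  Subjects carrying
#' obliterated-CSF intervals are additionally re-segmented with the median
#' smoothing cascade enabled (reusing the same template matches) so the
#' effect of smoothing can be compared.
#'
#' @param configs list of [phantom_config]s (e.g. from [cohort_configs()]);
#'   the first subject provides the template database unless `rotate`.
#' @param n_slices matching stations per subject.
#' @param marking_sd in-plane drift (mm) of the emulated manual markings.
#' @param rotate if `TRUE`, every subject takes a turn as the template
#'   subject (`n * (n - 1)` segmentations); the default uses subject 1 only.
#' @param verbose print per-subject progress.
#' @return A `loo_report`: data frame `per_subject` with `db_subject`,
#'   `dice`, `dice_smooth` (`NA` where smoothing was not run), `md_mm`,
#'   `hd_mm`, `n_fallback`, and a `mean` row summary.
#' @export
loo_cohort <- function(configs, n_slices = 100, marking_sd = 0.3,
                       rotate = FALSE, verbose = FALSE) {
  stopifnot(length(configs) >= 2L)
  n <- length(configs)
  cases <- lapply(configs, generate_phantom)
  db_ids <- if (rotate) seq_len(n) else 1L
  rows <- NULL
  for (j in db_ids) {
    db <- build_template_db(gradient_magnitude(cases[[j]]$volume),
                            cases[[j]]$truth_mask,
                            subject_id = paste0("subject", j))
    for (i in setdiff(seq_len(n), j)) {
      cfg <- configs[[i]]
      case <- cases[[i]]
      markings <- jitter_markings(case, sd_mm = marking_sd,
                                  seed = cfg$seed + 17L)
      seg <- segment_cord(case$volume, markings, db, n_slices = n_slices)
      tsp <- truth_spline(case)
      d <- dice(seg$mask, case$truth_mask)
      md <- mean_centerline_distance(seg$refined_spline, tsp,
                                     slice_spacing = cfg$voxel_spacing[3])
      hd <- hausdorff(seg$mask, case$truth_mask)
      d_s <- NA_real_
      if (length(cfg$obliteration_intervals)) {
        seg_s <- smooth_segmentation(seg, case$volume)
        d_s <- dice(seg_s$mask, case$truth_mask)
      }
      if (verbose)
        message(sprintf("db %d -> subject %d: dice %.3f%s md %.3f mm hd %.2f mm",
                        j, i, d,
                        if (is.na(d_s)) "" else sprintf(" (smoothed %.3f)", d_s),
                        md, hd))
      rows <- rbind(rows,
                    data.frame(db_subject = j, subject = i, dice = d,
                               dice_smooth = d_s, md_mm = md, hd_mm = hd,
                               n_fallback = seg$meta$n_fallback))
    }
  }
  structure(list(per_subject = rows,
                 mean = data.frame(dice = mean(rows$dice),
                                   md_mm = mean(rows$md_mm),
                                   hd_mm = mean(rows$hd_mm))),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat("<loo_report>\n")
  print(x$per_subject, row.names = FALSE)
  cat(sprintf("mean: dice %.3f, md %.3f mm, hd %.2f mm\n",
              x$mean$dice, x$mean$md_mm, x$mean$hd_mm))
  invisible(x)
}
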