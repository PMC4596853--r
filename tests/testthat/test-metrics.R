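mask_from_idx <- function(dims, idx, spacing = c(1, 1, 1)) {
  a <- array(0L, dims)
  a[idx] <- 1L
  cord_mask(a, spacing)
}

test_that("dice follows the overlap formula", {
  dims <- c(8, 8, 4)
  a <- mask_from_idx(dims, 1:4)
  b <- mask_from_idx(dims, 3:6)
  expect_equal(dice(a, b), 2 * 2 / 8)   # |A|=|B|=4, overlap 2
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, mask_from_idx(dims, 101:104)), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(mask_from_idx(dims, integer(0)),
                    mask_from_idx(dims, integer(0))), "empty")
  expect_error(dice(a, mask_from_idx(c(4, 4, 4), 1:4)), "different grids")
})

test_that("mean centre-line distance matches analytic parallel lines", {
  sp1 <- cordseg:::new_spline(cbind(0, 0, seq(0, 20, length.out = 6)))
  sp2 <- cordseg:::new_spline(cbind(0.7, 0, seq(0, 20, length.out = 6)))
  expect_equal(mean_centerline_distance(sp1, sp2, slice_spacing = 0.5), 0.7,
               tolerance = 1e-9)
  expect_equal(mean_centerline_distance(sp1, sp1), 0, tolerance = 1e-12)

  # random spline pair vs direct per-slice evaluation summed over n-1
  set.seed(13)
  c1 <- cbind(rnorm(6, sd = 0.5), rnorm(6, sd = 0.5),
              seq(0, 20, length.out = 6))
  c2 <- cbind(rnorm(6, sd = 0.5), rnorm(6, sd = 0.5),
              seq(0, 20, length.out = 6))
  spa <- cordseg:::new_spline(c1); spb <- cordseg:::new_spline(c2)
  h <- 0.4
  zs <- seq(0, 20, by = h)
  pa <- cordseg:::spline_point_at_z(spa, zs)
  pb <- cordseg:::spline_point_at_z(spb, zs)
  d <- sqrt(rowSums((pa[, 1:2] - pb[, 1:2])^2))
  expect_equal(mean_centerline_distance(spa, spb, slice_spacing = h),
               sum(d[-1]) / (length(zs) - 1), tolerance = 1e-9)
  expect_error(mean_centerline_distance(sp1, spa, z_range = c(100, 120)),
               "overlap")
})

test_that("hausdorff matches analytic and brute-force oracles", {
  dims <- c(20, 20, 10)
  a <- mask_from_idx(dims, cbind(5, 5, 5))
  b <- mask_from_idx(dims, cbind(8, 9, 5))
  expect_equal(hausdorff(a, b), 5)  # offset (3, 4, 0)
  expect_equal(hausdorff(a, a), 0)

  # two random ~20-voxel blobs vs O(n^2) brute force over all voxel pairs
  set.seed(14)
  ia <- cbind(sample(3:18, 20, TRUE), sample(3:18, 20, TRUE),
              sample(2:9, 20, TRUE))
  ib <- cbind(sample(3:18, 20, TRUE), sample(3:18, 20, TRUE),
              sample(2:9, 20, TRUE))
  spc <- c(0.5, 0.5, 0.8)
  ma <- mask_from_idx(dims, ia, spc)
  mb <- mask_from_idx(dims, ib, spc)
  pa <- which(ma$data > 0, arr.ind = TRUE)
  pb <- which(mb$data > 0, arr.ind = TRUE)
  wa <- sweep(pa - 1, 2, spc, `*`)
  wb <- sweep(pb - 1, 2, spc, `*`)
  dmat <- matrix(0, nrow(wa), nrow(wb))
  for (i in seq_len(nrow(wa))) for (j in seq_len(nrow(wb)))
    dmat[i, j] <- sqrt(sum((wa[i, ] - wb[j, ])^2))
  brute <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
  # sparse blobs: every voxel is a boundary voxel, so surfaces = volumes
  expect_equal(hausdorff(ma, mb), brute, tolerance = 1e-9)
  expect_equal(hausdorff(ma, mb), hausdorff(mb, ma))
  expect_error(hausdorff(ma, mask_from_idx(dims, integer(0), spc)), "empty")
})

test_that("regions project markers onto the shared spline", {
  sp <- cordseg:::new_spline(cbind(0, 0, seq(0, 30, length.out = 8)))
  r <- region_from_markers(sp, c(0, 0, 5), c(0, 0, 12), label = "C4")
  expect_equal(r$z, c(5, 12), tolerance = 1e-6)
  # radial offset does not move the projected interval
  r2 <- region_from_markers(sp, c(4, 0, 5), c(0, 4, 12))
  expect_equal(r2$z, c(5, 12), tolerance = 1e-4)
  expect_error(region_from_markers(sp, c(0, 0, 12), c(0, 0, 5)),
               "rostral")
})

test_that("phantom rootlet markers demarcate contiguous increasing regions", {
  case <- tiny_clean_case()
  sp <- cordseg:::truth_spline(case)
  mk <- case$markers
  levels <- paste0("C", 3:8)
  z <- vapply(levels, function(l) {
    rows <- mk[mk$label == l, ]
    mean(vapply(seq_len(nrow(rows)), function(i)
      euclid_to_cyl(sp, unlist(rows[i, c("x", "y", "z")]))[["z"]],
      numeric(1)))
  }, numeric(1))
  regions <- lapply(1:5, function(i)
    structure(list(label = levels[i], z = c(z[i], z[i + 1])),
              class = "region_spec"))
  for (i in 1:4)
    expect_equal(regions[[i]]$z[2], regions[[i + 1]]$z[1])
  expect_true(all(vapply(regions, function(r) diff(r$z) > 0, logical(1))))
})

test_that("regional CSA recovers the analytic cylinder area", {
  # straight cylinder, radius 5 mm; region bounds off the slice planes
  cfg <- phantom_config(grid_shape = c(73L, 73L, 72L),
                        voxel_spacing = c(0.3906, 0.3906, 0.3),
                        amplitude = 0, radius_mm = rep(5, 4),
                        noise_sd = 0, edge_softening_mm = 0, seed = 21)
  case <- generate_phantom(cfg)
  sp <- cordseg:::truth_spline(case)
  csa <- regional_csa(case$truth_mask, sp, c(3.05, 12.05))
  expect_lt(abs(csa - pi * 25) / (pi * 25), 0.02)
  # doubling the region length on a uniform cylinder leaves CSA unchanged
  csa2 <- regional_csa(case$truth_mask, sp, c(3.05, 21.05))
  expect_lt(abs(csa2 - csa) / csa, 0.01)
  # empty mask -> 0
  empty <- cord_mask(array(0L, dim(case$truth_mask$data)),
                     case$truth_mask$spacing)
  expect_equal(regional_csa(empty, sp, c(3.05, 12.05)), 0)
  expect_error(regional_csa(case$truth_mask, sp, c(5, 5)), "zero arc length")
  expect_equal(csa_abs_diff(80, 72), 8)
})

test_that("a one-voxel band around a disk changes CSA by the closed form", {
  # enlarging a 5 mm disk by one voxel changes the area by pi((5+v)^2 - 25)
  v <- 0.5
  dims <- c(60, 60, 12); spc <- c(v, v, 1)
  ctr <- c((60 - 1) * v / 2, (60 - 1) * v / 2)
  disk <- function(r) {
    a <- array(0L, dims)
    for (k in 1:12) {
      xw <- (seq_len(60) - 1) * v
      d <- sqrt(outer((xw - ctr[1])^2, (xw - ctr[2])^2, `+`))
      a[, , k] <- (d <= r) * 1L
    }
    cord_mask(a, spc)
  }
  sp <- cordseg:::new_spline(cbind(ctr[1], ctr[2], seq(0, 11, length.out = 6)))
  c1 <- regional_csa(disk(5), sp, c(2, 9))
  c2 <- regional_csa(disk(5 + v), sp, c(2, 9))
  closed_form <- pi * ((5 + v)^2 - 25)
  # within voxelization tolerance: one perimeter band of the annulus
  expect_lt(abs((c2 - c1) - closed_form), 2 * pi * (5 + v) * v / 2)
})

test_that("cohort aggregation equals a hand-computed summary", {
  case <- tiny_clean_case()
  sp <- cordseg:::truth_spline(case)
  truth <- case$truth_mask
  # two perturbed copies: erode/dilate nothing, just shift one voxel in x
  shifted <- truth
  shifted$data <- truth$data[c(2:64, 64), , ]
  entries <- list(
    list(id = "a", mask_a = truth, mask_b = truth,
         spline_a = sp, spline_b = sp,
         regions = list(mid = structure(list(label = "mid", z = c(3, 9)),
                                        class = "region_spec"))),
    list(id = "b", mask_a = truth, mask_b = shifted,
         spline_a = sp, spline_b = sp, regions = list())
  )
  rep <- cohort_report(entries, slice_spacing = 0.4)
  expect_equal(rep$per_pair$dice[1], 1)
  expect_equal(rep$per_pair$md[1], 0)
  expect_lt(rep$per_pair$hd[1], 1e-5)
  d2 <- dice(truth, shifted)
  expect_equal(rep$per_pair$dice[2], d2)
  expect_equal(rep$summary$mean[rep$summary$metric == "dice"],
               mean(c(1, d2)))
  expect_equal(rep$summary$sd[rep$summary$metric == "dice"],
               sd(c(1, d2)))
  expect_equal(rep$csa$abs_diff, 0)

  prefix <- file.path(withr::local_tempdir(), "rep")
  write_metric_report(rep, prefix)
  expect_true(file.exists(paste0(prefix, "_pairs.csv")))
  back <- read.csv(paste0(prefix, "_summary.csv"))
  expect_equal(back$mean[back$metric == "dice"], mean(c(1, d2)))
})
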