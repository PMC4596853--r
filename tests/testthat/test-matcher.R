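test_that("ncc matches the direct formula and its invariances", {
  # direct evaluation of the printed formula on fixed small integer arrays
  f <- c(3, 1, 4, 1, 5, 9, 2, 6)
  t <- c(2, 7, 1, 8, 2, 8, 1, 8)
  n <- 8
  sf <- sqrt(sum((f - mean(f))^2) / n)
  st <- sqrt(sum((t - mean(t))^2) / n)
  direct <- sum((f - mean(f)) * (t - mean(t))) / (n * sf * st)
  expect_equal(as.numeric(ncc(f, t)), direct, tolerance = 1e-12)

  set.seed(5)
  x <- rnorm(70)
  expect_equal(as.numeric(ncc(x, x)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(ncc(x, -x)), -1, tolerance = 1e-12)
  expect_equal(as.numeric(ncc(x, 2.5 * x + 7)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(ncc(x, rev(x))), as.numeric(ncc(rev(x), x)),
               tolerance = 1e-12)
  # constant array: similarity defined as 0 and flagged
  z <- ncc(x, rep(4, 70))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(ncc(x, x[1:10]), "equal length")
})

make_db <- function(profiles, edges) {
  structure(list(profiles = profiles, edge_index = edges,
                 slice_index = rep(1L, nrow(profiles)),
                 angle_deg = rep(0, nrow(profiles)),
                 subject_id = rep("x", nrow(profiles)),
                 manifest = data.frame(subject = "x", n_slices = 1,
                                       n_profiles = nrow(profiles)),
                 n_samples = ncol(profiles)),
            class = "template_db")
}

test_that("exact copies in the database match at threshold 1.00", {
  set.seed(1)
  x <- rnorm(70)
  db <- make_db(matrix(rep(x, 60), 60, byrow = TRUE), rep(31L, 60))
  m <- find_matches(x, db)
  expect_equal(m$threshold, 1)
  expect_length(m$template_idx, 50)
  expect_true(all(abs(m$ncc - 1) < 1e-9))
  expect_false(m$fallback)
  expect_equal(m$inferred_edge, 31)
})

test_that("a constructed database stops the schedule at 0.98", {
  set.seed(2)
  u <- rnorm(70); u <- (u - mean(u)) / sqrt(sum((u - mean(u))^2))
  w <- unit_perp(u, 3)
  # 50 templates with NCC in (0.98, 1); 30 with NCC ~ 0.5
  phis <- acos(seq(0.985, 0.995, length.out = 50))
  high <- t(vapply(phis, function(p) cos(p) * u + sin(p) * w, numeric(70)))
  low <- t(vapply(1:30, function(i) 0.5 * u + sqrt(0.75) * unit_perp(u, 100 + i),
                  numeric(70)))
  db <- make_db(rbind(high, low), c(rep(20L, 50), rep(60L, 30)))
  m <- find_matches(u, db)
  expect_equal(m$threshold, 0.98)
  expect_length(m$template_idx, 50)
  expect_true(all(m$template_idx <= 50))
  expect_equal(m$inferred_edge, 20)
})

test_that("an anti-correlated database triggers the fallback", {
  set.seed(4)
  u <- rnorm(70)
  anti <- t(vapply(1:60, function(i) -u + rnorm(70, 0, 0.05), numeric(70)))
  db <- make_db(anti, rep(10L, 60))
  m <- find_matches(u, db)
  expect_true(m$fallback)
  expect_length(m$template_idx, 50)
  expect_true(is.na(m$threshold))
})

test_that("a database smaller than the target warns and uses all templates", {
  set.seed(6)
  x <- rnorm(70)
  db <- make_db(matrix(rep(x, 20), 20, byrow = TRUE), rep(12L, 20))
  expect_warning(m <- find_matches(x, db), "only 20")
  expect_length(m$template_idx, 20)
})

test_that("edge inference is the arithmetic mean of matched edges", {
  expect_equal(infer_edge(c(31, 31, 31)), 31)
  expect_equal(infer_edge(c(10, 20)), 15)
  set.seed(8)
  e <- sample(0:69, 50, replace = TRUE)
  expect_equal(infer_edge(e), sum(e) / 50)
})

make_field <- function(pos, index, mm = index * 0.39) {
  structure(list(slice_pos = pos, angle_deg = slice_angles(),
                 index = index, mm = mm,
                 status = matrix("matched", nrow(index), ncol(index)),
                 fallback = NULL),
            class = "edge_field")
}

test_that("edge-field interpolation is linear in z per angle", {
  idx <- rbind(rep(10, 179), rep(20, 179))
  f <- interpolate_edge_field(make_field(c(0, 10), idx))
  expect_equal(nrow(f$index), 11)
  expect_equal(f$index[6, ], rep(15, 179))
  expect_true(all(f$status[2:10, ] == "interpolated"))

  # random sparse field vs an independent piecewise-linear evaluation
  set.seed(11)
  pos <- sort(runif(8, 0, 30))
  idx <- matrix(runif(8 * 179, 5, 40), 8)
  f2 <- interpolate_edge_field(make_field(pos, idx))
  for (a in c(1, 57, 179)) {
    for (r in seq_along(f2$slice_pos)) {
      z <- f2$slice_pos[r]
      j <- findInterval(z, pos, rightmost.closed = TRUE)
      w <- (z - pos[j]) / (pos[j + 1] - pos[j])
      if (j == length(pos)) { j <- j - 1; w <- 1 }
      expect_equal(f2$index[r, a], (1 - w) * idx[j, a] + w * idx[j + 1, a],
                   tolerance = 1e-9)
    }
  }
  expect_error(interpolate_edge_field(make_field(5, matrix(1, 1, 179))),
               "at least 2")
})

test_that("the median cascade removes spikes and matches the sliding oracle", {
  const <- make_field(1:20, matrix(12, 20, 179))
  sm <- smooth_edge_field(const)
  expect_equal(sm$index, const$index)

  spike <- matrix(12, 20, 179)
  spike[10, 90] <- 60
  sm2 <- smooth_edge_field(make_field(1:20, spike), kernels = 5)
  expect_equal(sm2$index, matrix(12, 20, 179))

  # one ring of a random field, kernel 5 over theta: brute-force circular
  # sliding-window median oracle
  set.seed(12)
  row <- runif(179, 0, 69)
  f <- make_field(1:2, rbind(row, row))
  got <- smooth_edge_field(f, kernels = 5)$index[1, ]
  oracle <- vapply(seq_len(179), function(i) {
    win <- row[((i - 3):(i + 1)) %% 179 + 1]
    median(win)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_error(smooth_edge_field(f, kernels = 4), "odd")
})

test_that("rasterization reproduces disks, ellipses, and star convexity", {
  dims <- c(64, 64); sp <- c(0.4, 0.4)
  ctr <- c(12.8, 12.8)
  # constant edge distance: disk of radius 5, area within a perimeter band
  sl <- rasterize_slice(ctr, slice_angles(), rep(5, 179), dims, sp)
  expect_lt(abs(sum(sl) * prod(sp) - pi * 25), 2 * pi * 5 * sqrt(2) * max(sp))
  # all-zero edges: empty slice
  expect_equal(sum(rasterize_slice(ctr, slice_angles(), rep(0, 179), dims, sp)),
               0)

  # elliptical edge function: equals a direct per-voxel polar test
  a <- 6; b <- 3.5
  ang <- slice_angles() * pi / 180
  e <- a * b / sqrt((b * cos(ang))^2 + (a * sin(ang))^2)
  sl2 <- rasterize_slice(ctr, slice_angles(), e, dims, sp)
  xa <- c(slice_angles(), 360); ya <- c(e, e[1])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    dx <- (i - 1) * sp[1] - ctr[1]; dy <- (j - 1) * sp[2] - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    th <- (atan2(dy, dx) * 180 / pi) %% 360
    expect_identical(sl2[i, j], r <= approx(xa, ya, xout = th, rule = 2)$y)
  }

  # star convexity: along any ray the membership has one inside->outside
  # transition
  for (th in seq(0, 2 * pi, length.out = 36)) {
    rr <- seq(0, 8, by = 0.05)
    ii <- round((ctr[1] + rr * cos(th)) / sp[1]) + 1
    jj <- round((ctr[2] + rr * sin(th)) / sp[2]) + 1
    keep <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2]
    memb <- sl2[cbind(ii[keep], jj[keep])]
    expect_lte(sum(diff(memb) != 0), 1)
  }
})

test_that("recenter recovers the axis of a cylinder with 500 control points", {
  case <- tiny_clean_case()
  refined <- recenter(case$truth_mask)
  expect_equal(refined$n, 500)
  truth_xy <- case$truth_centerline[1, 1:2]
  pts <- evaluate_point(refined, seq(0.02, 0.98, length.out = 50))
  err <- sqrt((pts[, 1] - truth_xy[1])^2 + (pts[, 2] - truth_xy[2])^2)
  expect_lt(max(err), 0.5 * 0.4)
  expect_error(recenter(cord_mask(array(0L, c(5, 5, 5)), c(1, 1, 1))),
               ">= 4 axial slices")
})

test_that("self-segmentation reproduces the source phantom", {
  case <- selfseg_case()
  seg <- selfseg_segmentation()
  expect_gte(dice(seg$mask, case$truth_mask), 0.98)
  # matched stations correlate perfectly with their own templates
  expect_true(all(seg$meta$thresholds == 1))
  expect_equal(seg$meta$n_fallback, 0)
  expect_equal(seg$refined_spline$n, 500)

  # recentering a mask from an already-centred spline is a near fixed point
  refined <- seg$refined_spline
  again <- recenter(seg$mask)
  p1 <- evaluate_point(refined, seq(0.1, 0.9, length.out = 30))
  p2 <- evaluate_point(again, seq(0.1, 0.9, length.out = 30))
  expect_lt(mean(sqrt(rowSums((p1 - p2)^2))), 0.1 * 0.4)
})

test_that("smoothing barely changes a clean self-segmentation", {
  case <- selfseg_case()
  seg <- selfseg_segmentation()
  seg_s <- smooth_segmentation(seg, case$volume)
  n_diff <- sum(seg$mask$data != seg_s$mask$data)
  expect_lt(n_diff / length(seg$mask$data), 0.01)
  expect_gte(dice(seg$mask, seg_s$mask), 0.98)
})
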