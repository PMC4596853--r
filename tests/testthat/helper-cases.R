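# Shared phantom fixtures, generated once per test run and memoized.

.case_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.case_cache[[key]])) .case_cache[[key]] <- force(expr)
  .case_cache[[key]]
}

# small clean straight phantom: uniform 4 mm cord, isotropic 0.4 mm voxels
tiny_clean_case <- function() {
  cached("tiny_clean", generate_phantom(tiny_clean_config()))
}

tiny_clean_config <- function(...) {
  args <- list(grid_shape = c(64L, 64L, 40L),
               voxel_spacing = c(0.4, 0.4, 0.4),
               amplitude = 0, radius_mm = rep(4, 4),
               noise_sd = 0, seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_config, args)
}

# uniform straight phantom with >= 50 axial slices, so that every angle has
# at least 50 identical templates (self-matching reaches threshold 1.00)
selfseg_case <- function() {
  cached("selfseg",
         generate_phantom(phantom_config(grid_shape = c(64L, 64L, 60L),
                                         voxel_spacing = c(0.4, 0.4, 0.4),
                                         amplitude = 0, radius_mm = rep(4, 4),
                                         noise_sd = 0, seed = 11)))
}

selfseg_db <- function() {
  cached("selfseg_db", {
    case <- selfseg_case()
    build_template_db(gradient_magnitude(case$volume), case$truth_mask,
                      subject_id = "self")
  })
}

# segmentation of the self-consistency phantom with its own template db
selfseg_segmentation <- function() {
  cached("selfseg_seg", {
    case <- selfseg_case()
    segment_cord(case$volume, case$truth_centerline, selfseg_db(),
                 n_slices = 60)
  })
}

# straight synthetic gradient image with a bright ring at a given radius
ring_gradient_volume <- function(radius_mm = 5, dims = c(64L, 64L, 9L),
                                 spacing = c(0.4, 0.4, 0.4)) {
  cx <- (dims[1] - 1) * spacing[1] / 2
  cy <- (dims[2] - 1) * spacing[2] / 2
  xw <- (seq_len(dims[1]) - 1) * spacing[1]
  yw <- (seq_len(dims[2]) - 1) * spacing[2]
  d <- sqrt(outer((xw - cx)^2, (yw - cy)^2, `+`))
  ring <- exp(-((d - radius_mm) / 0.3)^2) * 100
  cord_volume(array(rep(ring, dims[3]), dims), spacing)
}

# independent scalar evaluation of the piecewise-cubic Hermite sum, used as
# the brute-force oracle for the vectorized curve implementation
cr_oracle <- function(ctrl, t) {
  N <- nrow(ctrl)
  P <- rbind(2 * ctrl[1, ] - ctrl[2, ], ctrl, 2 * ctrl[N, ] - ctrl[N - 1, ])
  u <- t * (N - 1)
  i <- min(floor(u), N - 2)
  s <- u - i
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  m1 <- 0.5 * (P[i + 3, ] - P[i + 1, ])
  m2 <- 0.5 * (P[i + 4, ] - P[i + 2, ])
  h00 * P[i + 2, ] + h10 * m1 + h01 * P[i + 3, ] + h11 * m2
}

# zero-mean unit-norm vector orthogonalized against another
unit_perp <- function(u, seed) {
  set.seed(seed)
  w <- stats::rnorm(length(u))
  w <- w - mean(w)
  w <- w - sum(w * u) / sum(u * u) * u
  w / sqrt(sum(w^2))
}
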