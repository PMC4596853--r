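#' Fit a Catmull-Rom centre-line spline to manual markings
#'
#' User markings approximating the cord centre (ordered rostral to caudal,
#' first marking at the ponto-medullary junction, the arc-length origin) are
#' thinned to `n_control` equally distributed control points and joined by a
#' piecewise-cubic Hermite (Catmull-Rom) curve.  Ghost points beyond each
#' end are placed so the end tangents point toward the adjacent control
#' point.  The curve is the axis of a generalized cylindrical coordinate
#' system `(z, theta, r)`: `z` is arc length in mm from the first marking,
#' `theta` the angle in the plane orthogonal to the local tangent measured
#' from the reference direction `d0`, and `r` the distance from the axis.
#'
#' @param markings n x 3 matrix (or list) of world-mm points along the cord
#'   centre, ordered rostral to caudal.
#' @param n_control number of control points to keep (default 20).
#' @param d0 unit reference direction defining `theta = 0`; must never be
#'   parallel to the curve tangent.
#' @param tangent_scale `"half"` (default) for the standard Catmull-Rom
#'   tangent `(P[i+1] - P[i-1]) / 2`, or `"count"` to scale the control-point
#'   differences by the number of control points instead.
#' @return An object of class `cord_spline`.
#' @export
fit_spline <- function(markings, n_control = 20, d0 = c(1, 0, 0),
                       tangent_scale = c("half", "count")) {
  tangent_scale <- match.arg(tangent_scale)
  pts <- as.matrix(markings)
  if (ncol(pts) != 3L) stop("markings must be n x 3 world points")
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2) > 1e-16)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(unique(pts)) < 4L)
    stop("need at least 4 distinct markings, got ", nrow(unique(pts)))
  m <- nrow(pts)
  if (m < n_control) {
    if (m >= 4L) {
      warning("only ", m, " distinct markings; using all of them as ",
              "control points")
      ctrl <- pts
    } else {
      stop("need at least 4 distinct markings, got ", m)
    }
  } else {
    idx <- unique(round(seq(1, m, length.out = n_control)))
    ctrl <- pts[idx, , drop = FALSE]
  }
  new_spline(ctrl, d0 = d0, tangent_scale = tangent_scale)
}

# build a cord_spline directly from control points (>= 4)
new_spline <- function(ctrl, d0 = c(1, 0, 0), tangent_scale = "half",
                       samples_per_segment = 80L) {
  ctrl <- as.matrix(ctrl)
  n <- nrow(ctrl)
  if (n < 4L) stop("need at least 4 control points, got ", n)
  d0 <- as.numeric(d0)
  d0 <- d0 / sqrt(sum(d0^2))
  ghosts <- rbind(2 * ctrl[1, ] - ctrl[2, ],
                  ctrl,
                  2 * ctrl[n, ] - ctrl[n - 1, ])
  sp <- structure(list(control = ctrl, ghosts = ghosts, n = n, d0 = d0,
                       tangent_scale = tangent_scale),
                  class = "cord_spline")
  # dense arc-length table (cumulative trapezoid of |dp/dt|)
  tt <- seq(0, 1, length.out = (n - 1L) * samples_per_segment + 1L)
  pts <- eval_spline(sp, tt)
  dp <- eval_spline(sp, tt, derivative = TRUE)
  speed <- sqrt(rowSums(dp^2))
  h <- diff(tt)
  s <- c(0, cumsum(h * (speed[-1] + speed[-length(speed)]) / 2))
  # tangent direction must never be parallel to d0 anywhere on the table
  tan_unit <- dp / speed
  ortho <- sqrt(pmax(0, 1 - (tan_unit %*% d0)^2))
  if (any(ortho < 1e-6))
    stop("reference direction d0 is (near-)parallel to the spline tangent")
  sp$table <- list(t = tt, s = s, points = pts)
  sp$total_length <- s[length(s)]
  if (any(diff(s) <= 0)) stop("degenerate spline: arc length not increasing")
  sp
}

#' @export
print.cord_spline <- function(x, ...) {
  cat(sprintf("<cord_spline> %d control points, length %.2f mm\n",
              x$n, x$total_length))
  invisible(x)
}

# Hermite basis (and derivatives) of the local parameter
hermite_h <- function(s, deriv = FALSE) {
  if (!deriv)
    cbind(h00 = 2 * s^3 - 3 * s^2 + 1, h10 = s^3 - 2 * s^2 + s,
          h01 = -2 * s^3 + 3 * s^2,    h11 = s^3 - s^2)
  else
    cbind(h00 = 6 * s^2 - 6 * s, h10 = 3 * s^2 - 4 * s + 1,
          h01 = -6 * s^2 + 6 * s, h11 = 3 * s^2 - 2 * s)
}

# vectorized curve (or d/dt) evaluation; t is clamped to [0, 1]
eval_spline <- function(sp, t, derivative = FALSE) {
  n <- sp$n
  t <- pmin(pmax(t, 0), 1)
  u <- t * (n - 1)
  i <- pmin(floor(u), n - 2)           # segment index 0 .. n-2
  tl <- u - i
  g <- sp$ghosts                        # row k+1 holds P_k (P_0 at row 1)
  P0 <- g[i + 1L, , drop = FALSE]
  P1 <- g[i + 2L, , drop = FALSE]
  P2 <- g[i + 3L, , drop = FALSE]
  P3 <- g[i + 4L, , drop = FALSE]
  k <- if (identical(sp$tangent_scale, "count")) n else 0.5
  ma <- k * (P2 - P0)
  mb <- k * (P3 - P1)
  H <- hermite_h(tl, deriv = derivative)
  out <- H[, 1] * P1 + H[, 2] * ma + H[, 3] * P2 + H[, 4] * mb
  if (derivative) out <- out * (n - 1)  # chain rule d(local)/dt
  out
}

#' Evaluate the centre-line curve
#'
#' @param sp a [cord_spline][fit_spline].
#' @param t curve parameter in `[0, 1)`; values outside are clamped with a
#'   warning.
#' @return `evaluate_point`: n x 3 matrix of world points.
#'   `spline_tangent`: n x 3 matrix of unit tangents.
#' @export
evaluate_point <- function(sp, t) {
  if (any(t < 0 | t > 1)) {
    warning("spline parameter outside [0,1) clamped")
    t <- pmin(pmax(t, 0), 1)
  }
  eval_spline(sp, t)
}

#' @rdname evaluate_point
#' @export
spline_tangent <- function(sp, t) {
  if (any(t < 0 | t > 1)) {
    warning("spline parameter outside [0,1) clamped")
    t <- pmin(pmax(t, 0), 1)
  }
  dp <- eval_spline(sp, t, derivative = TRUE)
  dp / sqrt(rowSums(dp^2))
}

#' Arc length along the centre line
#'
#' `s(t)` is the curve length in mm from the first marking (the
#' ponto-medullary junction analogue, `z = 0`) to parameter `t`, computed by
#' dense trapezoidal quadrature cached at spline construction.
#'
#' @inheritParams evaluate_point
#' @param t parameter in `[0, 1]`.
#' @return Arc length(s) in mm.
#' @export
arc_length <- function(sp, t) {
  t <- pmin(pmax(t, 0), 1)
  stats::approx(sp$table$t, sp$table$s, xout = t, rule = 2)$y
}

# inverse of arc length: parameter t with s(t) = z
arc_to_t <- function(sp, z) {
  stats::approx(sp$table$s, sp$table$t, xout = z, rule = 2)$y
}

# orthonormal frame at parameter t: unit tangent, e1 (theta = 0), e2
spline_frame <- function(sp, t) {
  tan <- as.numeric(spline_tangent(sp, t))
  d0 <- sp$d0
  e1 <- d0 - sum(d0 * tan) * tan     # tangent x (d0 x tangent)
  ne1 <- sqrt(sum(e1^2))
  if (ne1 < 1e-9) stop("d0 parallel to tangent; theta undefined")
  e1 <- e1 / ne1
  e2 <- c(tan[2] * e1[3] - tan[3] * e1[2],
          tan[3] * e1[1] - tan[1] * e1[3],
          tan[1] * e1[2] - tan[2] * e1[1])
  list(tangent = tan, e1 = e1, e2 = e2)
}

#' Convert a world point to generalized cylindrical coordinates
#'
#' Finds `t*`, the parameter of the closest point on the curve, and returns
#' `z = s(t*)`, the angle `theta` of the offset vector measured from the
#' projection of `d0` into the plane orthogonal to the tangent, and
#' `r`, the distance to the curve.  The arccos of the paper's formulation is
#' resolved to a full `[0, 2*pi)` angle by the sign of the out-of-plane
#' component, so all 179 radial directions are distinct.
#'
#' @inheritParams evaluate_point
#' @param x world point (length 3) .
#' @param max_r capture-region bound in mm; larger offsets are rejected
#'   because the nearest-point problem is no longer guaranteed unique.
#' @return Named numeric `c(z, theta, r)` (mm, radians, mm) with the
#'   nearest parameter in attribute `"t_star"`.
#' @export
euclid_to_cyl <- function(sp, x, max_r = 30) {
  x <- as.numeric(x)
  d2 <- rowSums((sp$table$points - rep(x, each = nrow(sp$table$points)))^2)
  j <- which.min(d2)
  tt <- sp$table$t
  lo <- tt[max(1L, j - 1L)]
  hi <- tt[min(length(tt), j + 1L)]
  f <- function(t) sum((as.numeric(eval_spline(sp, t)) - x)^2)
  t_star <- if (hi > lo) stats::optimize(f, c(lo, hi), tol = 1e-10)$minimum
            else tt[j]
  # golden-section search never lands on the interval ends; take whichever
  # of {end points, interior minimum} is closest
  cand <- c(t_star, lo, hi)
  t_star <- cand[which.min(vapply(cand, f, numeric(1)))]
  p <- as.numeric(eval_spline(sp, t_star))
  u <- x - p
  r <- sqrt(sum(u^2))
  fr <- spline_frame(sp, t_star)
  if (r > max_r)
    stop(sprintf("point at r = %.1f mm exceeds the %.0f mm capture region",
                 r, max_r))
  boundary <- t_star < 1e-9 || t_star > 1 - 1e-9
  if (boundary && r > 1e-9 && abs(sum(u * fr$tangent)) > 1e-3 * r)
    stop("point projects beyond the spline ends (out of domain)")
  theta <- atan2(sum(u * fr$e2), sum(u * fr$e1)) %% (2 * pi)
  if (r < 1e-12) theta <- 0
  structure(c(z = arc_length(sp, t_star), theta = theta, r = r),
            t_star = t_star)
}

#' Convert cylindrical coordinates back to a world point
#'
#' @inheritParams euclid_to_cyl
#' @param cyl named numeric `c(z, theta, r)`.
#' @return World point (length 3).
#' @export
cyl_to_euclid <- function(sp, cyl) {
  z <- cyl[["z"]]; theta <- cyl[["theta"]]; r <- cyl[["r"]]
  if (z < -1e-9 || z > sp$total_length + 1e-9)
    stop(sprintf("z = %.3f mm beyond the spline length %.3f mm",
                 z, sp$total_length))
  t_star <- arc_to_t(sp, z)
  fr <- spline_frame(sp, t_star)
  as.numeric(eval_spline(sp, t_star)) +
    r * (cos(theta) * fr$e1 + sin(theta) * fr$e2)
}

# bulk projection used by regional CSA: arc-length z (and radius r) of the
# nearest curve point for an n x 3 matrix of world points, via the dense
# table with parabolic refinement of the squared distance
project_to_spline <- function(sp, pts, chunk = 4096L) {
  pts <- as.matrix(pts)
  tabp <- sp$table$points
  tt <- sp$table$t
  m <- nrow(tabp)
  z <- numeric(nrow(pts)); r <- numeric(nrow(pts))
  for (start in seq(1L, nrow(pts), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(pts))
    P <- pts[idx, , drop = FALSE]
    # squared distances chunk x table
    d2 <- outer(rowSums(P^2), rowSums(tabp^2), `+`) - 2 * P %*% t(tabp)
    j <- max.col(-d2, ties.method = "first")
    rows <- seq_along(idx)
    t_best <- tt[j]
    interior <- j > 1L & j < m
    if (any(interior)) {
      ji <- j[interior]; ri <- rows[interior]
      y0 <- d2[cbind(ri, ji - 1L)]
      y1 <- d2[cbind(ri, ji)]
      y2 <- d2[cbind(ri, ji + 1L)]
      den <- y0 - 2 * y1 + y2
      off <- ifelse(den > 1e-300, 0.5 * (y0 - y2) / den, 0)
      off <- pmin(pmax(off, -0.5), 0.5)
      t_best[interior] <- tt[ji] + off * (tt[ji + 1L] - tt[ji])
    }
    p_best <- eval_spline(sp, t_best)
    z[idx] <- arc_length(sp, t_best)
    r[idx] <- sqrt(rowSums((P - p_best)^2))
  }
  list(z = z, r = r)
}

#' Serialize / restore a spline for provenance
#'
#' @inheritParams evaluate_point
#' @param path JSON file path.
#' @return `spline_to_json`: `path`, invisibly; `spline_from_json`: a
#'   [cord_spline][fit_spline].
#' @export
spline_to_json <- function(sp, path) {
  jsonlite::write_json(list(control_points = sp$control, d0 = sp$d0,
                            tangent_scale = sp$tangent_scale),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname spline_to_json
#' @export
spline_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_spline(obj$control_points, d0 = obj$d0,
             tangent_scale = obj$tangent_scale)
}
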