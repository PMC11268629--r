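# Parametric 3D B-splines with arc-length reparametrisation. The curve is
# fit per coordinate on a chord-length parameter in [0, 1]; a dense
# cumulative-chord table then maps curve parameter to Euclidean arc length,
# so samples can be placed equidistantly in real space rather than in
# parameter space.

#' Fit a parametric 3D spline through ordered points
#'
#' Fits one B-spline per coordinate against the normalised cumulative
#' chord-length parameter of the input points. With `smoothing = 0` the
#' curve interpolates the points exactly (in order); with `smoothing > 0` a
#' penalised least-squares fit is used (second-difference penalty on the
#' control points, weight `smoothing`), trading fidelity for smoothness.
#' The requested polynomial degree is demoted to `M - 1` when fewer points
#' than `order + 1` are supplied.
#'
#' An arc-length table is built by densely sampling the curve
#' (`max(1000, 10 * M * (degree + 1))` uniform parameter values, cumulative
#' chordal sums); it backs [spline_length()], [sample_equidistant()] and the
#' equidistance guarantees of the picking tools.
#'
#' @param points M x 3 matrix of ordered (x, y, z) points, M >= 2.
#' @param order Polynomial degree requested, 1-5 (3 = cubic).
#' @param smoothing Non-negative smoothing weight; 0 interpolates.
#' @return An object of class `spline3d`.
#' @export
fit_spline3d <- function(points, order = 3, smoothing = 0) {
  points <- as_points_matrix(points)
  m <- nrow(points)
  if (m < 2) abort_argument("at least 2 points are required to fit a spline")
  if (!all(is.finite(points))) abort_argument("spline points must be finite")
  if (!is.numeric(order) || length(order) != 1 || order < 1 || order > 5) {
    abort_argument("order must be an integer between 1 and 5")
  }
  if (!is.numeric(smoothing) || length(smoothing) != 1 || smoothing < 0) {
    abort_argument("smoothing must be a non-negative number")
  }
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-m, , drop = FALSE])^2))
  if (sum(seg) < 1e-12) abort_argument("all points coincide")

  degree <- max(1L, min(as.integer(order), m - 1L))
  ord <- degree + 1L

  # chord-length parameters; nudge duplicates apart so the design matrix
  # stays non-singular when consecutive picks coincide
  tt <- c(0, cumsum(seg)) / sum(seg)
  if (any(diff(tt) <= 0)) {
    tt <- tt + seq(0, 1, length.out = m) * 1e-9
    tt <- (tt - tt[1]) / (tt[m] - tt[1])
  }

  # clamped knot vector with de Boor averaged interior knots: guarantees the
  # Schoenberg-Whitney conditions, so the interpolation system is invertible
  n_interior <- m - ord
  interior <- if (n_interior > 0) {
    vapply(seq_len(n_interior),
           function(j) mean(tt[(j + 1):(j + degree)]), numeric(1))
  } else numeric(0)
  knots <- c(rep(0, ord), interior, rep(1, ord))

  basis <- splines::splineDesign(knots, tt, ord = ord)
  control <- if (smoothing > 0) {
    nc <- ncol(basis)
    pen <- diff(diag(nc), differences = min(2L, nc - 1L))
    solve(crossprod(basis) + smoothing * crossprod(pen),
          crossprod(basis, points))
  } else {
    solve(basis, points)
  }

  sp <- structure(
    list(control_points = control, knots = knots, degree = degree,
         order = as.integer(order), smoothing = smoothing,
         data_points = points, params = tt),
    class = "spline3d")

  n_dense <- max(1000L, 10L * m * (degree + 1L))
  td <- seq(0, 1, length.out = n_dense)
  pd <- spline_position(sp, td)
  len <- c(0, cumsum(sqrt(rowSums((pd[-1, , drop = FALSE] -
                                     pd[-n_dense, , drop = FALSE])^2))))
  sp$arc_table <- list(t = td, length = len)
  sp
}

#' @export
print.spline3d <- function(x, ...) {
  cat(sprintf(
    "<spline3d> %d control points | degree %d | smoothing %g | length %.4g\n",
    nrow(x$control_points), x$degree, x$smoothing, spline_length(x)))
  invisible(x)
}

#' Evaluate a spline (or its derivative) at given parameters
#'
#' @param spline A [fit_spline3d()] object.
#' @param t Parameter values in `[0, 1]` (clamped).
#' @param deriv Derivative order (0 = position).
#' @return K x 3 matrix of positions (or derivative vectors).
#' @export
spline_position <- function(spline, t, deriv = 0) {
  t <- pmin(pmax(as.numeric(t), 0), 1)
  # derivatives: stay inside the right-closed end of the basis support
  if (deriv > 0) t <- pmin(t, 1 - 1e-9)
  b <- splines::splineDesign(spline$knots, t, ord = spline$degree + 1L,
                             derivs = rep(deriv, length(t)))
  out <- b %*% spline$control_points
  colnames(out) <- c("x", "y", "z")
  out
}

#' @rdname spline_position
#' @export
spline_derivative <- function(spline, t) spline_position(spline, t, deriv = 1)

#' Total Euclidean arc length of a spline
#' @param spline A [fit_spline3d()] object.
#' @return Length in voxel units.
#' @export
spline_length <- function(spline) {
  tail(spline$arc_table$length, 1)
}

# invert the arc-length table: parameters at the requested arc lengths
arc_to_param <- function(spline, s) {
  tab <- spline$arc_table
  keep <- c(TRUE, diff(tab$length) > 0)
  stats::approx(tab$length[keep], tab$t[keep], xout = s, rule = 2,
                ties = "ordered")$y
}

#' Sample a spline at equal Euclidean arc-length steps
#'
#' Places `K = max(2, round(L / spacing) + 1)` samples at arc lengths
#' `j * L / (K - 1)`, so consecutive samples are equidistant in Euclidean
#' space (the spacing is adjusted to divide the total length exactly; exact
#' equidistance is preferred over the nominal spacing value). Both endpoints
#' are always included.
#'
#' @param spline A [fit_spline3d()] object.
#' @param spacing Requested inter-sample distance (> 0), voxel units.
#' @return List with `points` (K x 3 matrix), `t` (parameter values) and
#'   `spacing` (the realised spacing `L / (K - 1)`).
#' @export
sample_equidistant <- function(spline, spacing) {
  if (!is.numeric(spacing) || length(spacing) != 1 || !is.finite(spacing) ||
      spacing <= 0) {
    abort_argument("spacing must be a positive number")
  }
  total <- spline_length(spline)
  k <- max(2L, as.integer(round(total / spacing)) + 1L)
  s <- seq(0, total, length.out = k)
  t <- arc_to_param(spline, s)
  list(points = spline_position(spline, t), t = t,
       spacing = total / (k - 1))
}

#' Twist-free moving frames along a spline
#'
#' Builds rotation-minimising frames by the double-reflection
#' (parallel-transport) method: each frame is a proper rotation whose third
#' column (local Z) is the unit tangent, and consecutive frames carry no
#' rotation about the tangent beyond what the curve itself imposes. The
#' initial normal is deterministic: the coordinate axis with the smallest
#' tangent component, projected into the normal plane. On a straight
#' segment along +z every frame is the identity.
#'
#' @param spline A [fit_spline3d()] object.
#' @param t Ordered parameter values in `[0, 1]`.
#' @return 3 x 3 x K array of rotation matrices (columns = local x, y, z).
#' @export
frames_along <- function(spline, t) {
  t <- as.numeric(t)
  if (any(t < -1e-9 | t > 1 + 1e-9)) {
    abort_argument("frame parameters must lie in [0, 1]")
  }
  k <- length(t)
  pos <- spline_position(spline, t)
  tan_raw <- spline_derivative(spline, t)
  norms <- sqrt(rowSums(tan_raw^2))
  if (any(norms < 1e-12)) {
    abort_numerical(sprintf(
      "degenerate (zero) tangent at parameter t = %.6g",
      t[which(norms < 1e-12)[1]]))
  }
  tang <- tan_raw / norms

  frames <- array(0, dim = c(3, 3, k))
  t0 <- tang[1, ]
  axis <- diag(3)[, which.min(abs(t0))]
  r <- normalize3(axis - sum(axis * t0) * t0)
  frames[, , 1] <- cbind(r, cross3(t0, r), t0)

  if (k > 1) {
    for (i in seq_len(k - 1)) {
      x0 <- pos[i, ]; x1 <- pos[i + 1, ]
      ti <- tang[i, ]; tn <- tang[i + 1, ]
      v1 <- x1 - x0
      c1 <- sum(v1^2)
      if (c1 < 1e-24) {
        rl <- r; tl <- ti
      } else {
        rl <- r - (2 / c1) * sum(v1 * r) * v1
        tl <- ti - (2 / c1) * sum(v1 * ti) * v1
      }
      v2 <- tn - tl
      c2 <- sum(v2^2)
      rn <- if (c2 < 1e-24) rl else rl - (2 / c2) * sum(v2 * rl) * v2
      # re-orthogonalise against drift
      rn <- normalize3(rn - sum(rn * tn) * tn)
      frames[, , i + 1] <- cbind(rn, cross3(tn, rn), tn)
      r <- rn
    }
  }
  frames
}
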