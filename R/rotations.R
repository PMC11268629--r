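# Elementary rotation matrices (degrees, right-handed, active) used by the
# helical lattice generator and the Euler-angle conversions.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Elementary rotation matrices
#'
#' Proper rotation matrices about the coordinate axes, with the angle in
#' degrees. These are active right-handed rotations: `rot_z(90)` maps the
#' x axis onto the y axis.
#'
#' @param angle Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_z <- function(angle) {
  a <- deg2rad(angle)
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(angle) {
  a <- deg2rad(angle)
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rot_z
#' @export
rot_x <- function(angle) {
  a <- deg2rad(angle)
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

# TRUE when R is orthonormal with det +1 to `tol`.
is_rotation_matrix <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) && all(is.finite(R)) &&
    abs(det(R) - 1) < tol &&
    max(abs(crossprod(R) - diag(3))) < tol
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort_numerical("cannot normalise a zero-length vector")
  v / n
}
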