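# Euler-angle conventions of the particle file formats. Orientation
# matrices in this package map reference-frame basis vectors onto particle
# basis vectors; the format conventions are defined relative to that:
#
#   relion_zyz  (rot, tilt, psi):     R = Rz(-rot)  Ry(-tilt) Rz(-psi)
#   dynamo_zxz  (tdrot, tilt, narot): R = Rz(-tdrot) Rx(-tilt) Rz(-narot)
#
# so that R^T is the familiar "rotate the reference onto the particle"
# ZYZ/ZXZ product of the positive angles. matrix_to_euler() is the exact
# inverse away from gimbal lock; at gimbal lock the third angle is set to 0
# and the first absorbs the full in-plane rotation.

EULER_CONVENTIONS <- c("relion_zyz", "dynamo_zxz")

#' Convert Euler angles to an orientation matrix
#'
#' @param angles Numeric vector of 3 angles in degrees: (rot, tilt, psi)
#'   for `relion_zyz`, (tdrot, tilt, narot) for `dynamo_zxz`.
#' @param convention One of `"relion_zyz"`, `"dynamo_zxz"`.
#' @return 3 x 3 rotation matrix (reference -> particle semantics).
#' @export
euler_to_matrix <- function(angles, convention = "relion_zyz") {
  if (!is.numeric(angles) || length(angles) != 3 || !all(is.finite(angles))) {
    abort_argument("angles must be 3 finite numbers (degrees)")
  }
  switch(match_convention(convention),
    relion_zyz = rot_z(-angles[1]) %*% rot_y(-angles[2]) %*% rot_z(-angles[3]),
    dynamo_zxz = rot_z(-angles[1]) %*% rot_x(-angles[2]) %*% rot_z(-angles[3]))
}

match_convention <- function(convention) {
  if (!is.character(convention) || length(convention) != 1 ||
      !convention %in% EULER_CONVENTIONS) {
    abort_argument(sprintf("unknown Euler convention; supported: %s",
                           paste(EULER_CONVENTIONS, collapse = ", ")))
  }
  convention
}

#' Convert an orientation matrix to Euler angles
#'
#' Exact inverse of [euler_to_matrix()] away from gimbal lock (tilt of 0 or
#' 180 degrees); at gimbal lock the decomposition is degenerate and the
#' documented rule applies: the first angle (rot / tdrot) is 0 and the
#' third (psi / narot) carries the whole in-plane rotation.
#'
#' @param R 3 x 3 proper rotation matrix.
#' @param convention One of `"relion_zyz"`, `"dynamo_zxz"`.
#' @return Numeric vector of 3 angles in degrees.
#' @export
matrix_to_euler <- function(R, convention = "relion_zyz") {
  if (!is_rotation_matrix(R, tol = 1e-4)) {
    abort_argument("R must be a proper rotation matrix")
  }
  # q = t(R) = Rz(a) Rm(b) Rz(c) with a = third format angle (psi/narot),
  # c = first format angle (rot/tdrot)
  q <- t(R)
  eps <- 1e-9
  if (match_convention(convention) == "relion_zyz") {
    # q = Rz(a) Ry(b) Rz(c)
    sb <- sqrt(q[1, 3]^2 + q[2, 3]^2)
    b <- atan2(sb, q[3, 3])
    if (sb > eps) {
      a <- atan2(q[2, 3], q[1, 3])
      c <- atan2(q[3, 2], -q[3, 1])
    } else if (q[3, 3] > 0) {
      b <- 0; c <- 0
      a <- atan2(q[2, 1], q[1, 1])
    } else {
      b <- pi; c <- 0
      a <- atan2(-q[2, 1], -q[1, 1])
    }
  } else {
    # q = Rz(a) Rx(b) Rz(c)
    sb <- sqrt(q[3, 1]^2 + q[3, 2]^2)
    b <- atan2(sb, q[3, 3])
    if (sb > eps) {
      a <- atan2(q[1, 3], -q[2, 3])
      c <- atan2(q[3, 1], q[3, 2])
    } else if (q[3, 3] > 0) {
      b <- 0; c <- 0
      a <- atan2(q[2, 1], q[1, 1])
    } else {
      b <- pi; c <- 0
      a <- atan2(q[2, 1], q[1, 1])
    }
  }
  rad2deg(c(c, b, a))
}
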