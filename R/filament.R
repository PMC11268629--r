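# Helical filament picking: a single spline through manual picks becomes a
# helical lattice of oriented particle poses. The procedure is: (1) fit the
# spline, (2) sample it equidistantly at the helical rise, (3) rotate each
# rotation-minimising frame by the accumulated twist, (4) shift radially
# along the twisted local X axis, (5) replicate by cyclic symmetry about
# the filament axis.

#' Helical lattice parameters
#'
#' @param rise Axial translation between consecutive subunits, voxel units
#'   along the filament (> 0).
#' @param twist Rotation about the filament axis per rise step, degrees.
#' @param radius Radial offset of the particles from the filament axis,
#'   voxel units (>= 0).
#' @param symmetry Cyclic symmetry order n (Cn), integer >= 1.
#' @return An object of class `helical_params`.
#' @export
helical_params <- function(rise, twist = 0, radius = 0, symmetry = 1) {
  if (!is.numeric(rise) || length(rise) != 1 || !is.finite(rise) || rise <= 0) {
    abort_argument("rise must be a positive number")
  }
  if (!is.numeric(twist) || length(twist) != 1 || !is.finite(twist)) {
    abort_argument("twist must be a finite number (degrees)")
  }
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius < 0) {
    abort_argument("radius must be a non-negative number")
  }
  symmetry <- as.integer(symmetry)
  if (is.na(symmetry) || symmetry < 1) {
    abort_argument("symmetry must be an integer >= 1")
  }
  structure(list(rise = rise, twist = twist, radius = radius,
                 symmetry = symmetry), class = "helical_params")
}

#' Generate helical particle poses along a filament spline
#'
#' Base samples are placed Euclidean-equidistantly along the spline at
#' spacing `rise` (the rise is measured along the filament axis, not along
#' the helical path). Sample `j` (counting from 0 at the filament start)
#' carries the orientation `F_j %*% rot_z(j * twist)` where `F_j` is the
#' rotation-minimising frame, so every pose's local Z axis is the filament
#' tangent. A positive `radius` shifts each pose off the axis along its
#' twisted local X axis, tracing a helical point pattern. With Cn symmetry
#' each pose is replicated n times by additional local-Z rotations of
#' `360/n` degrees: the copies share the axis point and are azimuthally
#' uniform around it.
#'
#' @param spline A [fit_spline3d()] through the manual filament picks.
#' @param params A [helical_params()].
#' @param experiment_id Identifier of the source tomogram.
#' @param filament_id Integer id stored in the feature table.
#' @param pixel_spacing Angstrom per voxel (0 = unknown).
#' @return A [pose_set()] with `n * K` poses and features `filament`,
#'   `axis_index` (j, 0-based) and `sym_index` (m, 0-based).
#' @export
generate_helical_poses <- function(spline, params, experiment_id = "",
                                   filament_id = 1L, pixel_spacing = 0) {
  if (!inherits(params, "helical_params")) {
    abort_argument("params must be a helical_params object")
  }
  samp <- sample_equidistant(spline, params$rise)
  k <- nrow(samp$points)
  frames <- frames_along(spline, samp$t)
  n <- params$symmetry

  total <- n * k
  positions <- matrix(0, total, 3)
  orientations <- array(0, dim = c(3, 3, total))
  axis_index <- integer(total)
  sym_index <- integer(total)

  idx <- 0L
  for (j in seq_len(k) - 1L) {
    fj <- frames[, , j + 1L]
    axis_point <- samp$points[j + 1L, ]
    for (m in seq_len(n) - 1L) {
      idx <- idx + 1L
      o <- fj %*% rot_z(j * params$twist + 360 * m / n)
      orientations[, , idx] <- o
      positions[idx, ] <- axis_point + params$radius * o[, 1]
      axis_index[idx] <- j
      sym_index[idx] <- m
    }
  }

  pose_set(positions, orientations,
           data.frame(filament = rep(as.integer(filament_id), total),
                      axis_index = axis_index, sym_index = sym_index),
           experiment_id = experiment_id, pixel_spacing = pixel_spacing)
}

#' Equidistant polyline along a filament spline
#'
#' Dense ordered samples for display or export of the filament path.
#'
#' @param spline A [fit_spline3d()] object.
#' @param spacing Inter-point distance (> 0), voxel units.
#' @return K x 3 matrix of ordered points.
#' @export
filament_polyline <- function(spline, spacing) {
  sample_equidistant(spline, spacing)$points
}
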