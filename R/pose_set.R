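# The universal particle currency: positions + orientations + per-particle
# feature table + experiment id + pixel spacing. Every picking tool produces
# one of these and every particle writer consumes one.

as_points_matrix <- function(points, what = "points") {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(points) || length(points) == 0) {
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  if (is.vector(points) && length(points) == 3) points <- matrix(points, 1, 3)
  if (!is.matrix(points) || ncol(points) != 3) {
    abort_argument(sprintf("%s must be an N x 3 matrix", what))
  }
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  points
}

#' Construct a particle pose set
#'
#' A `pose_set` bundles particle positions, orientations, a per-particle
#' feature table, an experiment identifier and the pixel spacing of the
#' source tomogram. Positions are in voxel units of the source tomogram,
#' axis order (x, y, z), zero-based (voxel centre 0 is coordinate 0), which
#' is the convention of the particle file formats. Orientation matrices map
#' reference-frame basis vectors onto particle basis vectors: column `i` of
#' an orientation is the particle's i-th basis vector expressed in tomogram
#' coordinates. Use [particle_to_reference()] for the inverse view.
#'
#' @param positions N x 3 numeric matrix of (x, y, z) voxel coordinates.
#' @param orientations 3 x 3 x N array of proper rotation matrices, or
#'   `NULL` for identity orientations.
#' @param features data.frame with N rows of per-particle metadata, or
#'   `NULL` for a bare particle-index column.
#' @param experiment_id Identifier tying the particles to a tomogram.
#' @param pixel_spacing Pixel spacing in Angstrom per voxel; `0` encodes
#'   "unknown" and is propagated, never guessed.
#' @return An object of class `pose_set`.
#' @seealso [poses_from_points()], [select_poses()], [validate_poses()]
#' @export
pose_set <- function(positions, orientations = NULL, features = NULL,
                     experiment_id = "", pixel_spacing = 0) {
  positions <- as_points_matrix(positions, "positions")
  n <- nrow(positions)
  if (is.null(orientations)) {
    orientations <- array(diag(3), dim = c(3, 3, n))
  }
  if (!is.array(orientations) || length(dim(orientations)) != 3 ||
      !all(dim(orientations)[1:2] == c(3, 3))) {
    abort_argument("orientations must be a 3 x 3 x N array")
  }
  if (dim(orientations)[3] != n) {
    abort_argument("orientations count must match the number of positions")
  }
  if (is.null(features)) {
    features <- data.frame(particle = seq_len(n))
  }
  if (!is.data.frame(features) || nrow(features) != n) {
    abort_argument("features must be a data.frame with one row per pose")
  }
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1 ||
      is.na(pixel_spacing) || pixel_spacing < 0) {
    abort_argument("pixel_spacing must be a single non-negative number")
  }
  structure(
    list(positions = positions, orientations = orientations,
         features = features, experiment_id = as.character(experiment_id),
         pixel_spacing = pixel_spacing),
    class = "pose_set")
}

#' Number of poses in a pose set
#' @param poses A [pose_set()].
#' @return Integer count.
#' @export
n_poses <- function(poses) nrow(poses$positions)

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf(
    "<pose_set> %d poses | experiment '%s' | pixel spacing %s\n",
    n_poses(x), x$experiment_id,
    if (x$pixel_spacing > 0) sprintf("%g A/px", x$pixel_spacing) else "unknown"))
  cat("features:", paste(names(x$features), collapse = ", "), "\n")
  invisible(x)
}

#' Particle-frame view of the orientations
#'
#' Returns the transposed (inverse) orientation matrices, i.e. the rotations
#' mapping particle basis vectors back onto the reference frame. This is the
#' convention some averaging packages expect.
#'
#' @param poses A [pose_set()].
#' @return 3 x 3 x N array of inverse rotations.
#' @export
particle_to_reference <- function(poses) {
  out <- poses$orientations
  for (i in seq_len(dim(out)[3])) out[, , i] <- t(poses$orientations[, , i])
  out
}

#' Create identity-oriented poses from clicked points
#'
#' The simplest picking operation: each manually clicked point becomes a
#' particle at that position with the identity orientation, ready for
#' refinement downstream.
#'
#' @param points N x 3 matrix of (x, y, z) voxel coordinates.
#' @param experiment_id Identifier of the source tomogram.
#' @param pixel_spacing Angstrom per voxel (0 = unknown).
#' @return A [pose_set()] with identity orientations and a particle-index
#'   feature column.
#' @export
poses_from_points <- function(points, experiment_id = "", pixel_spacing = 0) {
  points <- as_points_matrix(points)
  if (!all(is.finite(points))) {
    abort_argument("points must be finite coordinates")
  }
  pose_set(points, experiment_id = experiment_id,
           pixel_spacing = pixel_spacing)
}

#' Select poses by a numeric feature range
#'
#' Keeps the poses whose feature value `v` satisfies `lo <= v <= hi`
#' (order preserved), the library form of selecting a region of a feature
#' histogram or scatter plot.
#'
#' @param poses A [pose_set()].
#' @param feature Name of a numeric feature column.
#' @param lo,hi Inclusive bounds; use `-Inf`/`Inf` for one-sided selection.
#' @return The sub-`pose_set` within the range.
#' @export
select_poses <- function(poses, feature, lo = -Inf, hi = Inf) {
  if (!feature %in% names(poses$features)) {
    abort_key(sprintf("feature column '%s' not found", feature))
  }
  v <- poses$features[[feature]]
  if (!is.numeric(v)) {
    abort_argument(sprintf("feature column '%s' is not numeric", feature))
  }
  if (lo > hi) abort_argument("lo must not exceed hi")
  keep <- which(!is.na(v) & v >= lo & v <= hi)
  subset_poses(poses, keep)
}

subset_poses <- function(poses, idx) {
  pose_set(poses$positions[idx, , drop = FALSE],
           poses$orientations[, , idx, drop = FALSE],
           poses$features[idx, , drop = FALSE],
           poses$experiment_id, poses$pixel_spacing)
}

# Concatenate pose sets sharing experiment id / spacing.
bind_poses <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  if (length(sets) == 1) return(sets[[1]])
  pos <- do.call(rbind, lapply(sets, `[[`, "positions"))
  ori <- array(unlist(lapply(sets, `[[`, "orientations")), c(3, 3, nrow(pos)))
  feats <- do.call(rbind, lapply(sets, `[[`, "features"))
  rownames(feats) <- NULL
  pose_set(pos, ori, feats, sets[[1]]$experiment_id, sets[[1]]$pixel_spacing)
}

#' Validate a pose set against its invariants
#'
#' Checks every structural invariant: finite positions, orientations that
#' are proper rotations (determinant +1, orthonormal to 1e-6), and a feature
#' table with one row per pose. Reporting operation: it never throws.
#'
#' @param poses A [pose_set()].
#' @return Character vector of violations, each naming the offending field
#'   and row; empty when the object is valid.
#' @export
validate_poses <- function(poses) {
  out <- character(0)
  pos <- poses$positions
  n <- nrow(pos)
  bad <- which(!apply(is.finite(pos), 1, all))
  for (i in bad) out <- c(out, sprintf("positions: non-finite value at row %d", i))
  ori <- poses$orientations
  if (!is.array(ori) || length(dim(ori)) != 3 || dim(ori)[3] != n) {
    out <- c(out, "orientations: wrong shape")
  } else {
    for (i in seq_len(n)) {
      R <- ori[, , i]
      if (!all(is.finite(R))) {
        out <- c(out, sprintf("orientations: non-finite matrix at row %d", i))
        next
      }
      if (abs(det(R) - 1) >= 1e-6) {
        out <- c(out, sprintf("orientations: determinant != +1 at row %d", i))
      }
      if (max(abs(crossprod(R) - diag(3))) >= 1e-6) {
        out <- c(out, sprintf("orientations: not orthonormal at row %d", i))
      }
    }
  }
  if (!is.data.frame(poses$features) || nrow(poses$features) != n) {
    out <- c(out, "features: row count does not match number of poses")
  }
  if (!(is.numeric(poses$pixel_spacing) && length(poses$pixel_spacing) == 1 &&
        !is.na(poses$pixel_spacing) && poses$pixel_spacing >= 0)) {
    out <- c(out, "pixel_spacing: must be a non-negative scalar")
  }
  out
}
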