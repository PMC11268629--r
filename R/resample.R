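# Surface-guided volume resampling ("straightening"): the tomogram is
# sampled on the surface grid along each node's normal into a regular box,
# turning a curved membrane into a flat slab whose central slice is the
# annotated surface itself.

#' Resampling parameters
#'
#' @param thickness Total extent sampled along the normal, voxel units
#'   (> 0, and at least `step`).
#' @param step Sampling interval along the normal, voxel units (> 0).
#' @return An object of class `resample_spec`.
#' @export
resample_spec <- function(thickness, step) {
  if (!is.numeric(thickness) || length(thickness) != 1 || thickness <= 0 ||
      !is.numeric(step) || length(step) != 1 || step <= 0) {
    abort_argument("thickness and step must be positive numbers")
  }
  if (thickness < step) abort_argument("thickness must be at least step")
  structure(list(thickness = thickness, step = step),
            class = "resample_spec")
}

# Trilinear interpolation of `data` ([x, y, z], 1-based) at zero-based
# coordinates `coords` (N x 3). Out-of-bounds samples get `fill`.
trilinear_sample <- function(data, coords, fill) {
  d <- dim(data)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  inb <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  out <- rep(fill, nrow(coords))
  valid <- which(inb)
  if (length(valid) == 0) return(list(values = out, inside = inb))
  x <- x[valid]; y <- y[valid]; z <- z[valid]
  i0 <- pmin(floor(x), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(y), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(z), d[3] - 2); k0 <- pmax(k0, 0)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  at <- function(i, j, k) data[1 + i + j * d[1] + k * d[1] * d[2]]
  v <-
    at(i0,     j0,     k0)     * (1 - fx) * (1 - fy) * (1 - fz) +
    at(i0 + 1, j0,     k0)     * fx       * (1 - fy) * (1 - fz) +
    at(i0,     j0 + 1, k0)     * (1 - fx) * fy       * (1 - fz) +
    at(i0 + 1, j0 + 1, k0)     * fx       * fy       * (1 - fz) +
    at(i0,     j0,     k0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(i0 + 1, j0,     k0 + 1) * fx       * (1 - fy) * fz +
    at(i0,     j0 + 1, k0 + 1) * (1 - fx) * fy       * fz +
    at(i0 + 1, j0 + 1, k0 + 1) * fx       * fy       * fz
  out[valid] <- v
  list(values = out, inside = inb)
}

#' Straighten a volume along an annotated surface
#'
#' Samples the volume by trilinear interpolation at
#' `node + offset * normal` for `W = 2 * floor(thickness / (2 * step)) + 1`
#' symmetric offsets `(w - (W - 1) / 2) * step`; W is forced odd so the
#' annotated surface is exactly the central slice. The output array has
#' shape `(W, U, V)`: the normal axis first (so "average along Z" is a mean
#' over axis 1), then the two grid axes. Samples falling outside the volume
#' are filled with the volume mean; the companion `valid` array marks real
#' samples so means can ignore the filled voxels.
#'
#' @param volume An [image_volume()] (3D).
#' @param grid A [build_surface_grid()] result.
#' @param spec A [resample_spec()].
#' @return An [image_volume()] of shape (W, U, V) with
#'   `pixel_spacing = step * input spacing`, plus a `valid` logical array
#'   of the same shape attached as field `$valid`.
#' @export
resample_along_surface <- function(volume, grid, spec) {
  if (!inherits(spec, "resample_spec")) {
    abort_argument("spec must be a resample_spec")
  }
  data <- image_data(volume)
  if (length(dim(data)) != 3) abort_argument("volume must be 3D")
  w <- 2L * floor(spec$thickness / (2 * spec$step)) + 1L
  offsets <- (seq_len(w) - 1 - (w - 1) / 2) * spec$step
  d <- dim(grid$grid_points)
  u <- d[1]; v <- d[2]
  nodes <- matrix(grid$grid_points, u * v, 3)
  normals <- matrix(grid$normals, u * v, 3)
  fill <- mean(data)

  out <- array(0, dim = c(w, u, v))
  valid <- array(FALSE, dim = c(w, u, v))
  for (wi in seq_len(w)) {
    coords <- nodes + offsets[wi] * normals
    s <- trilinear_sample(data, coords, fill)
    out[wi, , ] <- array(s$values, c(u, v))
    valid[wi, , ] <- array(s$inside, c(u, v))
  }
  res <- image_volume(out, pixel_spacing = spec$step * volume$pixel_spacing,
                      experiment_id = volume$experiment_id)
  res$valid <- valid
  res
}

#' Mean projection of a volume along an axis
#'
#' Arithmetic mean along the given axis; when the volume carries a `valid`
#' mask (from [resample_along_surface()]) only valid voxels contribute, and
#' pixels with no valid sample fall back to the plain mean.
#'
#' @param volume An [image_volume()].
#' @param axis Axis to average over (1-based).
#' @return An [image_volume()] of one lower rank.
#' @export
project_mean <- function(volume, axis = 1) {
  data <- image_data(volume)
  nd <- length(dim(data))
  if (!is.numeric(axis) || length(axis) != 1 || axis < 1 || axis > nd) {
    abort_argument(sprintf("axis must be between 1 and %d", nd))
  }
  keep <- setdiff(seq_len(nd), axis)
  if (!is.null(volume$valid)) {
    num <- apply(data * volume$valid, keep, sum)
    den <- apply(volume$valid, keep, sum)
    plain <- apply(data, keep, mean)
    proj <- ifelse(den > 0, num / pmax(den, 1), plain)
  } else {
    proj <- apply(data, keep, mean)
  }
  image_volume(as.array(proj), pixel_spacing = volume$pixel_spacing,
               experiment_id = volume$experiment_id)
}
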