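# Deterministic synthetic fixtures: analytic helices, membrane sheets and
# sparse label stacks with known ground truth, used by the test-suite, the
# documentation and the CLI `fixtures` subcommand. All randomness is
# controlled by an explicit seed and restricted to a local RNG scope.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

# accumulate a Gaussian blob of amplitude 1 at zero-based centre `c0`
add_blob <- function(data, c0, sigma) {
  d <- dim(data)
  r <- ceiling(4 * sigma)
  rng <- lapply(1:3, function(a) {
    lo <- max(0, floor(c0[a] - r)); hi <- min(d[a] - 1, ceiling(c0[a] + r))
    lo:hi
  })
  if (any(vapply(rng, length, integer(1)) == 0)) return(data)
  dx2 <- (rng[[1]] - c0[1])^2
  dy2 <- (rng[[2]] - c0[2])^2
  dz2 <- (rng[[3]] - c0[3])^2
  blob <- exp(-(outer(outer(dx2, dy2, "+"), dz2, "+")) / (2 * sigma^2))
  data[rng[[1]] + 1, rng[[2]] + 1, rng[[3]] + 1] <-
    data[rng[[1]] + 1, rng[[2]] + 1, rng[[3]] + 1] + blob
  data
}

#' Synthetic helical filament volume with ground-truth poses
#'
#' Places Gaussian blobs on an analytic helix (axis along +z through the
#' volume centre) with the given rise, twist and radius, optionally adding
#' Gaussian noise. Returns the volume, the ground-truth poses (positions on
#' the helix; orientations are the axis frame twisted by `j * twist`, i.e.
#' exactly what the filament picker should recover), and the axis points a
#' user would click.
#'
#' @param size Volume dimensions (x, y, z) in voxels.
#' @param rise Axial spacing between blobs, voxels.
#' @param twist Azimuthal rotation between blobs, degrees.
#' @param radius Helix radius, voxels.
#' @param blob_sigma Gaussian blob width, voxels.
#' @param noise_sigma Additive Gaussian noise level (0 = none).
#' @param margin Axial margin kept free at both ends, voxels.
#' @param seed RNG seed (noise only).
#' @return List with `volume` ([image_volume()]), `poses` ([pose_set()]),
#'   `axis_points` (matrix) and `params` ([helical_params()]).
#' @export
make_helix_volume <- function(size = c(48, 48, 64), rise = 6, twist = 30,
                              radius = 8, blob_sigma = 1.5, noise_sigma = 0,
                              margin = 4, seed = 1) {
  size <- as.integer(size)
  if (length(size) != 3 || any(size < 8)) {
    abort_argument("size must be 3 dimensions of at least 8 voxels")
  }
  cx <- (size[1] - 1) / 2
  cy <- (size[2] - 1) / 2
  if (cx - radius - 4 * blob_sigma < 0 || cx + radius + 4 * blob_sigma >
        size[1] - 1 || cy + radius + 4 * blob_sigma > size[2] - 1) {
    abort_argument("helix (radius + blob) exceeds the volume cross-section")
  }
  z <- seq(margin, size[3] - 1 - margin, by = rise)
  if (length(z) < 2) abort_argument("volume too short for the given rise")
  k <- length(z)
  theta <- (seq_len(k) - 1) * twist
  positions <- cbind(cx + radius * cos(deg2rad(theta)),
                     cy + radius * sin(deg2rad(theta)), z)
  orientations <- array(0, dim = c(3, 3, k))
  for (j in seq_len(k)) orientations[, , j] <- rot_z(theta[j])

  data <- array(0, dim = size)
  for (j in seq_len(k)) data <- add_blob(data, positions[j, ], blob_sigma)
  if (noise_sigma > 0) {
    data <- data + with_seed(seed, array(stats::rnorm(prod(size),
                                                      sd = noise_sigma), size))
  }
  list(
    volume = image_volume(data, experiment_id = "helix_fixture"),
    poses = pose_set(positions, orientations,
                     data.frame(axis_index = seq_len(k) - 1L),
                     experiment_id = "helix_fixture"),
    axis_points = cbind(cx, cy, z),
    params = helical_params(rise = rise, twist = twist, radius = radius))
}

#' Synthetic membrane sheet with per-slice pick strips
#'
#' Builds an analytic surface cutting across the z-slices, samples point
#' strips on it (what a user would click slice by slice, with optional
#' in-plane jitter), renders the surface into a volume as a shell of
#' Gaussian cross-section, and returns the exact normal and signed-distance
#' functions for oracle comparisons.
#'
#' Kinds: `"plane"` is the tilted plane `x = x0 + slope * z`; `"sine"` adds
#' a sinusoidal corrugation `amplitude * sin(2 * pi * y / period)` to it;
#' `"cylinder"` is the cylinder of the given radius with axis along z.
#'
#' @param kind Surface shape: `"plane"`, `"sine"`, or `"cylinder"`.
#' @param size Volume dimensions (x, y, z) in voxels.
#' @param n_slices Number of annotated z-slices.
#' @param points_per_strip Picks per slice.
#' @param slope Plane/sine tilt dx/dz.
#' @param amplitude,period Sine corrugation parameters (voxels).
#' @param radius Cylinder radius (voxels).
#' @param shell_sigma Gaussian shell width of the rendered volume.
#' @param jitter In-plane pick jitter standard deviation, voxels.
#' @param seed RNG seed (jitter only).
#' @return List with `volume`, `strips` (list of matrices), `normal_at`
#'   (function: N x 3 points -> N x 3 unit normals), `sdist_at` (signed
#'   distance function) and the geometry parameters.
#' @export
make_membrane_fixture <- function(kind = c("plane", "sine", "cylinder"),
                                  size = c(64, 64, 64), n_slices = 5,
                                  points_per_strip = 6, slope = 1,
                                  amplitude = 3, period = 32, radius = 50,
                                  shell_sigma = 1.5, jitter = 0, seed = 1) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  zs <- round(seq(2, size[3] - 3, length.out = n_slices))

  if (kind %in% c("plane", "sine")) {
    amp <- if (kind == "plane") 0 else amplitude
    x0 <- (size[1] - 1) / 2 - slope * (size[3] - 1) / 2
    surf_x <- function(y, z) x0 + slope * z + amp * sin(2 * pi * y / period)
    strips <- lapply(zs, function(z) {
      y <- seq(4, size[2] - 5, length.out = points_per_strip)
      cbind(surf_x(y, z), y, z)
    })
    normal_at <- function(p) {
      p <- as_points_matrix(p)
      g <- cbind(1, -amp * (2 * pi / period) * cos(2 * pi * p[, 2] / period),
                 -slope)
      g / sqrt(rowSums(g^2))
    }
    sdist_at <- function(p) {
      p <- as_points_matrix(p)
      # exact only for the pure plane; first-order for the sine sheet
      (p[, 1] - surf_x(p[, 2], p[, 3])) /
        sqrt(1 + slope^2 + (amp * 2 * pi / period)^2 / 2)
    }
  } else {
    centre <- c((size[1] - 1) / 2, (size[2] - 1) / 2 - radius)
    theta <- seq(60, 120, length.out = points_per_strip)
    strips <- lapply(zs, function(z) {
      cbind(centre[1] + radius * cos(deg2rad(theta)),
            centre[2] + radius * sin(deg2rad(theta)), z)
    })
    normal_at <- function(p) {
      p <- as_points_matrix(p)
      g <- cbind(p[, 1] - centre[1], p[, 2] - centre[2], 0)
      g / sqrt(rowSums(g^2))
    }
    sdist_at <- function(p) {
      p <- as_points_matrix(p)
      sqrt((p[, 1] - centre[1])^2 + (p[, 2] - centre[2])^2) - radius
    }
  }

  if (jitter > 0) {
    strips <- with_seed(seed, lapply(strips, function(s) {
      s[, 1:2] <- s[, 1:2] + matrix(stats::rnorm(2 * nrow(s), sd = jitter),
                                    ncol = 2)
      s
    }))
  }

  coords <- expand.grid(x = seq_len(size[1]) - 1, y = seq_len(size[2]) - 1,
                        z = seq_len(size[3]) - 1)
  d <- sdist_at(as.matrix(coords))
  data <- array(exp(-d^2 / (2 * shell_sigma^2)), dim = size)

  list(volume = image_volume(data, experiment_id = "membrane_fixture"),
       strips = strips, normal_at = normal_at, sdist_at = sdist_at,
       kind = kind, slices = zs)
}

#' Synthetic sparse label stack for interpolation tests
#'
#' A 3D stack with annotated slices containing analytic disks (and, with
#' `two_labels`, disjoint squares under a second label id) at known slice
#' indices; every other slice is empty.
#'
#' @param size Stack dimensions (x, y, n_slices); slices along axis 3.
#' @param slices 1-based indices of the annotated slices.
#' @param radii Disk radius on each annotated slice (label 1).
#' @param centre Disk centre (x, y), zero-based; defaults to the middle.
#' @param two_labels Add a second label (squares) on the same slices?
#' @param square_half Half-width of the label-2 squares per slice.
#' @param square_centre Centre of the label-2 squares, zero-based.
#' @return A [labeled_volume()].
#' @export
make_label_stack <- function(size = c(64, 64, 11), slices = c(1, 11),
                             radii = c(4, 8), centre = NULL,
                             two_labels = FALSE, square_half = c(4, 6),
                             square_centre = NULL) {
  size <- as.integer(size)
  if (length(slices) != length(radii)) {
    abort_argument("slices and radii must have the same length")
  }
  if (any(slices < 1 | slices > size[3])) {
    abort_argument("annotated slice indices out of range")
  }
  if (is.null(centre)) centre <- c(size[1], size[2]) / 2 - 1 - size[1] / 4
  if (is.null(square_centre)) {
    square_centre <- c(size[1], size[2]) * 3 / 4 - 1
  }
  x <- seq_len(size[1]) - 1
  y <- seq_len(size[2]) - 1
  data <- array(0L, dim = size)
  for (k in seq_along(slices)) {
    disk <- outer((x - centre[1])^2, (y - centre[2])^2, "+") <= radii[k]^2
    slice <- matrix(0L, size[1], size[2])
    slice[disk] <- 1L
    if (two_labels) {
      sq <- outer(abs(x - square_centre[1]), abs(y - square_centre[2]),
                  pmax) <= square_half[min(k, length(square_half))]
      if (any(slice[sq] != 0L)) {
        abort_argument("label shapes overlap; move the square centre")
      }
      slice[sq] <- 2L
    }
    data[, , slices[k]] <- slice
  }
  labeled_volume(data)
}
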