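# Spline-grid surface model. Point strips picked on successive Z-slices are
# turned into a rectangular U x V lattice of equidistant surface points with
# full orientation frames:
#   1. one spline per strip,         2. equidistant samples on each,
#   3. integer-shift alignment of consecutive strips + padding to a
#      rectangle,                    4. splines through the matched columns
#      (perpendicular direction),    5. equidistant resampling of those,
#   6. a third spline family along the rows of the final grid,
#   7. tangents of the two crossing families -> surface normals and frames.

#' Align point strips by integer index shifts and pad to a rectangle
#'
#' Each consecutive pair of strips is aligned by brute-force search over all
#' integer shifts with at least two index-matched points, minimising the
#' mean Euclidean distance between matched points; ties are broken towards
#' the smaller absolute shift (then the smaller shift). Strips are then
#' padded on both ends to a common width by linear extrapolation of their
#' terminal segments, and the padded entries are flagged in a mask.
#'
#' @param strips List of >= 2 matrices (each N_i x 3, N_i >= 2) of ordered
#'   points, one strip per slice.
#' @return List with `offsets` (integer start column of each strip, 0-based),
#'   `points` (U x V x 3 array) and `padded` (U x V logical mask, `TRUE`
#'   where the node was extrapolated).
#' @export
align_strips <- function(strips) {
  if (!is.list(strips) || length(strips) < 2) {
    abort_argument("at least 2 strips are required")
  }
  strips <- lapply(strips, as_points_matrix, what = "strip")
  lens <- vapply(strips, nrow, integer(1))
  if (any(lens < 2)) abort_argument("every strip needs at least 2 points")

  u <- length(strips)
  rel <- integer(u)
  for (i in 2:u) rel[i] <- best_strip_shift(strips[[i - 1]], strips[[i]])
  offsets <- cumsum(rel)
  offsets <- offsets - min(offsets)
  width <- max(offsets + lens)

  points <- array(NA_real_, dim = c(u, width, 3))
  padded <- matrix(TRUE, u, width)
  for (i in seq_len(u)) {
    s <- strips[[i]]
    n <- lens[i]
    cols <- offsets[i] + seq_len(n)
    points[i, cols, ] <- s
    padded[i, cols] <- FALSE
    lead <- offsets[i]
    if (lead > 0) {
      step <- s[1, ] - s[2, ]
      for (j in seq_len(lead)) points[i, cols[1] - j, ] <- s[1, ] + j * step
    }
    trail <- width - offsets[i] - n
    if (trail > 0) {
      step <- s[n, ] - s[n - 1, ]
      for (j in seq_len(trail)) points[i, cols[n] + j, ] <- s[n, ] + j * step
    }
  }
  list(offsets = offsets, points = points, padded = padded)
}

# Best integer shift o of strip b relative to strip a: point j of b is
# matched with point j + o of a. Requires an overlap of >= 2 points.
best_strip_shift <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  best_o <- 0L; best_cost <- Inf
  for (o in seq(-(nb - 1L), na - 1L)) {
    jb <- seq_len(nb)
    ja <- jb + o
    sel <- ja >= 1L & ja <= na
    if (sum(sel) < 2L) next
    d <- sqrt(rowSums((b[sel, , drop = FALSE] -
                         a[ja[sel], , drop = FALSE])^2))
    cost <- mean(d)
    better <- cost < best_cost - 1e-12 ||
      (abs(cost - best_cost) <= 1e-12 &&
         (abs(o) < abs(best_o) || (abs(o) == abs(best_o) && o < best_o)))
    if (better) { best_cost <- cost; best_o <- o }
  }
  best_o
}

#' Build a spline-grid surface from per-slice point strips
#'
#' Runs the full surface construction: per-strip splines, equidistant
#' sampling at `spacing`, strip alignment and padding ([align_strips()]),
#' splines through the matched columns (the direction perpendicular to the
#' strips), equidistant resampling of those at `spacing` (each column is
#' sampled at equal fractions of its own arc length, with the common row
#' count set by the mean column length, so the grid stays rectangular), a
#' third spline family along the rows of the final grid, and per-node
#' orientation frames: local Z is the unit surface normal (normalised cross
#' product of the two tangent families), local X and Y follow from
#' Gram-Schmidt of the tangents. Normal signs are made continuous across
#' the grid, seeded at the first unpadded node.
#'
#' @param strips List of point strips (each N_i x 3, ordered as picked),
#'   one per slice, ordered by slice coordinate; or a single data frame /
#'   matrix with a fourth grouping column (see [strips_from_points()]).
#' @param spacing Requested inter-node distance, voxel units (> 0).
#' @param order Spline degree (1-5).
#' @param smoothing Non-negative smoothing weight (0 = interpolate).
#' @param experiment_id Identifier of the source tomogram.
#' @return An object of class `surface_grid` with fields `grid_points`
#'   (U x V x 3), `orientations` (3 x 3 x U x V), `padded_mask` (U x V),
#'   `tangents_u` / `tangents_v` (U x V x 3 unit tangents of the
#'   across-strip and along-strip families), `spacing`, `experiment_id`.
#' @export
build_surface_grid <- function(strips, spacing, order = 3, smoothing = 0,
                               experiment_id = "") {
  if (!is.list(strips) || is.data.frame(strips)) {
    strips <- strips_from_points(strips)
  }
  if (length(strips) < 2) abort_argument("at least 2 slice strips are required")
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    abort_argument("spacing must be a positive number")
  }

  step_guard <- function(step, expr) {
    tryCatch(expr, cryopick_error = function(e) {
      abort_numerical(sprintf("degenerate surface input at %s: %s",
                              step, conditionMessage(e)))
    })
  }

  # steps 1-3: spline per strip, equidistant samples
  rows <- lapply(strips, function(s) {
    sp <- step_guard("strip splines (step 2)", fit_spline3d(s, order, smoothing))
    sample_equidistant(sp, spacing)$points
  })

  # step 4: integer alignment + padding
  al <- align_strips(rows)
  u0 <- dim(al$points)[1]
  v <- dim(al$points)[2]

  # step 5-6: column splines (perpendicular to the strips), resampled
  col_splines <- lapply(seq_len(v), function(j) {
    step_guard("column splines (step 5)",
               fit_spline3d(al$points[, j, , drop = TRUE], order, smoothing))
  })
  col_len <- vapply(col_splines, spline_length, numeric(1))
  u <- max(2L, as.integer(round(mean(col_len) / spacing)) + 1L)

  grid <- array(0, dim = c(u, v, 3))
  tangents_u <- array(0, dim = c(u, v, 3))
  padded <- matrix(FALSE, u, v)
  for (j in seq_len(v)) {
    sp <- col_splines[[j]]
    tpar <- arc_to_param(sp, seq(0, spline_length(sp), length.out = u))
    grid[, j, ] <- spline_position(sp, tpar)
    d <- spline_derivative(sp, tpar)
    tangents_u[, j, ] <- d / sqrt(rowSums(d^2))
    # a resampled node counts as padded if its neighbourhood on the column
    # spline drew on any extrapolated strip node
    mval <- stats::approx(sp$params, as.numeric(al$padded[, j]), xout = tpar,
                          rule = 2, ties = "ordered")$y
    padded[, j] <- mval > 1e-9
  }

  # step 7: third family along the rows of the final grid
  tangents_v <- array(0, dim = c(u, v, 3))
  for (i in seq_len(u)) {
    sp <- step_guard("row splines (step 7)",
                     fit_spline3d(grid[i, , , drop = TRUE], order, smoothing))
    d <- spline_derivative(sp, sp$params)
    tangents_v[i, , ] <- d / sqrt(rowSums(d^2))
  }

  # step 8: normals and frames
  raw_normal <- array(0, dim = c(u, v, 3))
  for (i in seq_len(u)) {
    for (j in seq_len(v)) {
      nrm <- cross3(tangents_u[i, j, ], tangents_v[i, j, ])
      nn <- sqrt(sum(nrm^2))
      if (nn < 1e-9) {
        abort_numerical(sprintf(
          "degenerate surface: parallel tangents at grid node (%d, %d) (step 8)",
          i, j))
      }
      raw_normal[i, j, ] <- nrm / nn
    }
  }
  normal <- orient_normals(raw_normal, padded)

  orientations <- array(0, dim = c(3, 3, u, v))
  for (i in seq_len(u)) {
    for (j in seq_len(v)) {
      z <- normal[i, j, ]
      x <- tangents_u[i, j, ]
      x <- normalize3(x - sum(x * z) * z)
      orientations[, , i, j] <- cbind(x, cross3(z, x), z)
    }
  }

  structure(
    list(grid_points = grid, orientations = orientations,
         padded_mask = padded, tangents_u = tangents_u,
         tangents_v = tangents_v, normals = normal, spacing = spacing,
         experiment_id = as.character(experiment_id)),
    class = "surface_grid")
}

# Flip normal signs for continuity across the grid, seeded at the first
# unpadded node (scan order), whose raw cross-product sign is kept.
orient_normals <- function(raw, padded) {
  u <- dim(raw)[1]; v <- dim(raw)[2]
  out <- raw
  for (i in seq_len(u)) {
    for (j in seq_len(v)) {
      ref <- if (i > 1) out[i - 1, j, ] else if (j > 1) out[i, j - 1, ] else next
      if (sum(out[i, j, ] * ref) < 0) out[i, j, ] <- -out[i, j, ]
    }
  }
  out
}

#' @export
print.surface_grid <- function(x, ...) {
  d <- dim(x$grid_points)
  cat(sprintf(
    "<surface_grid> %d x %d nodes | spacing %g | %d padded | experiment '%s'\n",
    d[1], d[2], x$spacing, sum(x$padded_mask), x$experiment_id))
  invisible(x)
}

#' Group a picked point table into per-slice strips
#'
#' Splits an x,y,z(,group) point table into ordered strips: rows sharing a
#' grouping value (the fourth column when present, otherwise the z
#' coordinate) form one strip, in pick order; strips are ordered by their
#' slice coordinate.
#'
#' @param points Matrix or data frame with columns x, y, z and optionally a
#'   strip/group column.
#' @return List of N_i x 3 matrices.
#' @export
strips_from_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) < 3) {
    abort_argument("points must have at least 3 columns (x, y, z)")
  }
  group <- if (ncol(points) >= 4) points[, 4] else points[, 3]
  keys <- sort(unique(group))
  lapply(keys, function(k) {
    as_points_matrix(points[group == k, 1:3, drop = FALSE], "strip")
  })
}

#' Extract particle poses from a surface grid
#'
#' One pose per grid node: position = node, orientation = node frame (local
#' Z along the surface normal). Padded (extrapolated) nodes are excluded by
#' default since they do not correspond to annotated surface.
#'
#' @param grid A [build_surface_grid()] result.
#' @param include_padded Keep poses at padded nodes?
#' @param pixel_spacing Angstrom per voxel (0 = unknown).
#' @return A [pose_set()] with `grid_u` / `grid_v` feature columns.
#' @export
surface_poses <- function(grid, include_padded = FALSE, pixel_spacing = 0) {
  d <- dim(grid$grid_points)
  u <- d[1]; v <- d[2]
  keep <- which(if (include_padded) matrix(TRUE, u, v) else !grid$padded_mask,
                arr.ind = TRUE)
  keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
  n <- nrow(keep)
  positions <- matrix(0, n, 3)
  orientations <- array(0, dim = c(3, 3, n))
  for (r in seq_len(n)) {
    positions[r, ] <- grid$grid_points[keep[r, 1], keep[r, 2], ]
    orientations[, , r] <- grid$orientations[, , keep[r, 1], keep[r, 2]]
  }
  pose_set(positions, orientations,
           data.frame(grid_u = keep[, 1], grid_v = keep[, 2]),
           experiment_id = grid$experiment_id, pixel_spacing = pixel_spacing)
}

#' Triangle mesh of a surface grid
#'
#' Vertices are the grid nodes in row-major order (`v` fastest); each grid
#' quad is split into two triangles, wound so that the face normal points
#' along the stored node normals.
#'
#' @param grid A [build_surface_grid()] result with U, V >= 2.
#' @return List with `vertices` (UV x 3) and `faces`
#'   (2(U-1)(V-1) x 3 integer matrix of 1-based vertex indices).
#' @export
surface_mesh <- function(grid) {
  d <- dim(grid$grid_points)
  u <- d[1]; v <- d[2]
  if (u < 2 || v < 2) abort_argument("mesh needs a grid of at least 2 x 2")
  vertices <- matrix(0, u * v, 3)
  vid <- function(i, j) (i - 1L) * v + j
  for (i in seq_len(u)) for (j in seq_len(v)) {
    vertices[vid(i, j), ] <- grid$grid_points[i, j, ]
  }
  faces <- matrix(0L, 2L * (u - 1L) * (v - 1L), 3L)
  f <- 0L
  for (i in seq_len(u - 1L)) {
    for (j in seq_len(v - 1L)) {
      ref <- grid$normals[i, j, ]
      for (tri in list(c(vid(i, j), vid(i, j + 1L), vid(i + 1L, j)),
                       c(vid(i + 1L, j), vid(i, j + 1L), vid(i + 1L, j + 1L)))) {
        e1 <- vertices[tri[2], ] - vertices[tri[1], ]
        e2 <- vertices[tri[3], ] - vertices[tri[1], ]
        if (sum(cross3(e1, e2) * ref) < 0) tri <- tri[c(1, 3, 2)]
        f <- f + 1L
        faces[f, ] <- tri
      }
    }
  }
  list(vertices = vertices, faces = faces)
}

#' Write a mesh as a Wavefront OBJ file
#'
#' @param mesh A [surface_mesh()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  lines <- c(
    sprintf("v %.6f %.6f %.6f",
            mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
    sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]))
  writeLines(lines, path)
  invisible(path)
}
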