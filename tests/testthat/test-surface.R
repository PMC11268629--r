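grid_normals_matrix <- function(grid) {
  d <- dim(grid$grid_points)
  matrix(grid$normals, d[1] * d[2], 3)
}

grid_points_matrix <- function(grid) {
  d <- dim(grid$grid_points)
  matrix(grid$grid_points, d[1] * d[2], 3)
}

test_that("align_strips recovers integer offsets and pads to a rectangle", {
  a <- cbind(seq(0, 9), 0, 0)
  res <- align_strips(list(a, a))
  expect_equal(res$offsets, c(0, 0))
  expect_false(any(res$padded))

  # strip b = a advanced by one index: relative offset 1
  b <- cbind(seq(1, 10), 0, 1)
  res2 <- align_strips(list(a, b))
  expect_equal(diff(res2$offsets), 1)
  expect_equal(sum(res2$padded), 2)

  # widths 5 and 8 at matching starts: rectangle of width 8, 3 padded nodes
  s5 <- cbind(seq(0, 4), 0, 0)
  s8 <- cbind(seq(0, 7), 0, 1)
  res3 <- align_strips(list(s5, s8))
  expect_equal(dim(res3$points)[2], 8)
  expect_equal(sum(res3$padded), 3)
  expect_true(all(res3$padded[1, 6:8]))

  expect_error(align_strips(list(a)), class = "cryopick_argument_error")
})

test_that("alignment equals the exhaustive-search oracle on random scenarios", {
  set.seed(123)
  for (rep in 1:40) {
    na <- sample(4:10, 1)
    nb <- sample(4:10, 1)
    base <- cbind(cumsum(runif(max(na, nb) + 6, 0.5, 2)),
                  rnorm(max(na, nb) + 6, sd = 0.1), 0)
    start_a <- sample.int(4, 1)
    start_b <- sample.int(4, 1)
    a <- base[start_a:(start_a + na - 1), , drop = FALSE]
    b <- base[start_b:(start_b + nb - 1), , drop = FALSE]
    b[, 2] <- b[, 2] + 1  # next slice
    got <- align_strips(list(a, b))
    expect_equal(diff(got$offsets), oracle_best_shift(a, b),
                 info = sprintf("scenario %d", rep))
  }
})

test_that("padding extrapolates terminal segments linearly", {
  a <- cbind(seq(2, 6), 0, 0)        # will need leading pad of 2
  b <- cbind(seq(0, 6), 0, 1)
  res <- align_strips(list(a, b))
  col_a <- res$points[1, , 1]
  expect_equal(unname(col_a), seq(0, 6), tolerance = 1e-9)
  expect_true(all(res$padded[1, 1:2]))
})

test_that("tilted-plane strips reconstruct the analytic plane", {
  mb <- make_membrane_fixture("plane", n_slices = 5, points_per_strip = 6)
  g <- build_surface_grid(mb$strips, spacing = 4)
  pts <- grid_points_matrix(g)
  nrm <- grid_normals_matrix(g)
  true_n <- mb$normal_at(pts)
  free <- !as.vector(g$padded_mask)

  # normals within 1 degree of (1, 0, -1)/sqrt(2)
  errs <- sapply(which(free), function(i) angle_deg(nrm[i, ], true_n[i, ]))
  expect_lt(max(errs), 1)

  # node heights within 1 voxel RMS of the analytic plane
  expect_lt(sqrt(mean(mb$sdist_at(pts[free, ])^2)), 1)

  # nearest-neighbour spacing within 5% of requested, away from padded nodes
  d <- dim(g$grid_points)
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) {
    if (g$padded_mask[i, j]) next
    nb <- rbind(g$grid_points[i - 1, j, ], g$grid_points[i + 1, j, ],
                g$grid_points[i, j - 1, ], g$grid_points[i, j + 1, ])
    dist <- sqrt(rowSums((nb - rep(g$grid_points[i, j, ], each = 4))^2))
    expect_lt(abs(min(dist) - 4) / 4, 0.05)
  }

  # the two spline families are pointwise perpendicular on a plane
  coss <- abs(rowSums(matrix(g$tangents_u, d[1] * d[2], 3) *
                        matrix(g$tangents_v, d[1] * d[2], 3)))
  expect_lt(max(coss[free]), 0.05)
})

test_that("cylinder strips recover radial normals within 2 degrees", {
  mb <- make_membrane_fixture("cylinder", n_slices = 5, points_per_strip = 8,
                              radius = 50)
  g <- build_surface_grid(mb$strips, spacing = 4)
  pts <- grid_points_matrix(g)
  nrm <- grid_normals_matrix(g)
  true_n <- mb$normal_at(pts)
  free <- !as.vector(g$padded_mask)
  errs <- sapply(which(free), function(i) angle_deg(nrm[i, ], true_n[i, ]))
  expect_lt(max(errs), 2)
})

test_that("sinusoidal sheet is recovered within 1 voxel RMS", {
  mb <- make_membrane_fixture("sine", n_slices = 7, points_per_strip = 9,
                              amplitude = 3, period = 32)
  g <- build_surface_grid(mb$strips, spacing = 3)
  pts <- grid_points_matrix(g)
  free <- !as.vector(g$padded_mask)
  # sdist_at is first-order for the sine sheet; 1 voxel RMS still applies
  expect_lt(sqrt(mean(mb$sdist_at(pts[free, ])^2)), 1)
})

test_that("grid orientations satisfy the frame invariants", {
  set.seed(77)
  mb <- make_membrane_fixture("sine", n_slices = 5, points_per_strip = 7,
                              jitter = 0.3, seed = 9)
  g <- build_surface_grid(mb$strips, spacing = 4)
  d <- dim(g$grid_points)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    o <- g$orientations[, , i, j]
    expect_lt(abs(det(o) - 1), 1e-6)
    expect_lt(max(abs(crossprod(o) - diag(3))), 1e-6)
    expect_lt(abs(sum(o[, 3] * g$tangents_u[i, j, ])), 1e-3)
    expect_lt(abs(sum(o[, 3] * g$tangents_v[i, j, ])), 1e-3)
  }
  expect_equal(dim(g$padded_mask), d[1:2])
})

test_that("surface_poses excludes padded nodes and carries grid indices", {
  mb <- make_membrane_fixture("plane", n_slices = 4, points_per_strip = 5)
  g <- build_surface_grid(mb$strips, spacing = 5)
  d <- dim(g$grid_points)
  p_all <- surface_poses(g, include_padded = TRUE)
  p_free <- surface_poses(g)
  expect_equal(n_poses(p_all), d[1] * d[2])
  expect_equal(n_poses(p_free), d[1] * d[2] - sum(g$padded_mask))
  expect_valid_poses(p_all)
  expect_true(all(c("grid_u", "grid_v") %in% names(p_free$features)))

  # on a plane all pose local-Z agree pairwise within 1 degree
  z <- t(sapply(seq_len(n_poses(p_free)),
                function(i) p_free$orientations[, 3, i]))
  ref <- z[1, ]
  expect_lt(max(apply(z, 1, function(v) angle_deg(v, ref))), 1)
})

test_that("surface_mesh triangulates with consistent winding", {
  mb <- make_membrane_fixture("plane", n_slices = 4, points_per_strip = 5)
  g <- build_surface_grid(mb$strips, spacing = 5)
  mesh <- surface_mesh(g)
  d <- dim(g$grid_points)
  expect_equal(nrow(mesh$faces), 2 * (d[1] - 1) * (d[2] - 1))
  expect_true(all(mesh$faces >= 1 & mesh$faces <= nrow(mesh$vertices)))

  mean_n <- colMeans(grid_normals_matrix(g))
  mean_n <- mean_n / sqrt(sum(mean_n^2))
  for (f in seq_len(nrow(mesh$faces))) {
    v <- mesh$vertices[mesh$faces[f, ], ]
    fn <- c((v[2, 2] - v[1, 2]) * (v[3, 3] - v[1, 3]) -
              (v[2, 3] - v[1, 3]) * (v[3, 2] - v[1, 2]),
            (v[2, 3] - v[1, 3]) * (v[3, 1] - v[1, 1]) -
              (v[2, 1] - v[1, 1]) * (v[3, 3] - v[1, 3]),
            (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
              (v[2, 2] - v[1, 2]) * (v[3, 1] - v[1, 1]))
    fn <- fn / sqrt(sum(fn^2))
    expect_gt(sum(fn * mean_n), 0.99)
  }

  # 2x2 grid gives exactly 2 triangles
  g22 <- g
  g22$grid_points <- g$grid_points[1:2, 1:2, , drop = FALSE]
  g22$normals <- g$normals[1:2, 1:2, , drop = FALSE]
  expect_equal(nrow(surface_mesh(g22)$faces), 2)

  # OBJ export writes v/f lines
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(mesh, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(mesh$faces))
})

test_that("degenerate collinear input fails naming the step", {
  # both strips on the very same line: the cross-strip splines collapse
  strips <- list(cbind(0:4, 0, 0), cbind(0:4, 0, 0))
  err <- tryCatch(build_surface_grid(strips, 1), error = identity)
  expect_s3_class(err, "cryopick_numerical_error")
  expect_match(conditionMessage(err), "step")
})

test_that("strips_from_points groups by the fourth column or by z", {
  pts <- rbind(cbind(0:3, 0, 5), cbind(0:3, 1, 9))
  strips <- strips_from_points(pts)
  expect_length(strips, 2)
  expect_equal(nrow(strips[[1]]), 4)
  # explicit group column wins
  pts4 <- cbind(rbind(cbind(0:3, 0, 5), cbind(0:3, 1, 5)), rep(1:2, each = 4))
  expect_length(strips_from_points(pts4), 2)
})
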