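# flat surface grid on the plane z = z0 with +z normals, for controlled
# resampling checks
flat_grid <- function(u = 5, v = 6, z0 = 50, origin = c(15, 15), step = 5) {
  gp <- array(0, dim = c(u, v, 3))
  for (i in seq_len(u)) for (j in seq_len(v)) {
    gp[i, j, ] <- c(origin[1] + (i - 1) * step, origin[2] + (j - 1) * step, z0)
  }
  structure(list(
    grid_points = gp,
    orientations = array(diag(3), dim = c(3, 3, u, v)),
    padded_mask = matrix(FALSE, u, v),
    normals = array(rep(c(0, 0, 1), each = u * v), dim = c(u, v, 3)),
    spacing = step, experiment_id = "flat"), class = "surface_grid")
}

# volume whose intensity is the signed distance to the plane z = z0
sdist_volume <- function(n = 64, z0 = 50) {
  vol <- array(0, dim = c(n, n, n))
  for (z in seq_len(n)) vol[, , z] <- (z - 1) - z0
  image_volume(vol)
}

test_that("resample_spec validates its parameters", {
  expect_error(resample_spec(0, 1), class = "cryopick_argument_error")
  expect_error(resample_spec(10, 0), class = "cryopick_argument_error")
  expect_error(resample_spec(1, 2), class = "cryopick_argument_error")
  expect_equal(resample_spec(10, 1)$thickness, 10)
})

test_that("constant volumes resample to the constant", {
  vol <- image_volume(array(7, dim = c(64, 64, 64)))
  out <- resample_along_surface(vol, flat_grid(), resample_spec(10, 1))
  expect_equal(as.vector(image_data(out)), rep(7, length(image_data(out))))
})

test_that("straightening a signed-distance volume gives linear slice means", {
  out <- resample_along_surface(sdist_volume(), flat_grid(),
                                resample_spec(10, 1))
  data <- image_data(out)
  expect_equal(dim(data)[1], 11)
  for (w in 1:11) {
    slice <- data[w, , ]
    expect_lt(max(abs(slice - (w - 6))), 0.1)
  }
  expect_equal(apply(data, 1, mean), seq(-5, 5), tolerance = 0.1)
})

test_that("output spacing scales with the sampling step", {
  vol <- sdist_volume()
  vol$pixel_spacing <- 2
  out <- resample_along_surface(vol, flat_grid(), resample_spec(10, 0.5))
  expect_equal(out$pixel_spacing, 1)
  expect_equal(dim(image_data(out))[1], 2 * floor(10 / (2 * 0.5)) + 1)
})

test_that("out-of-bounds samples take the fill value without error", {
  vol <- image_volume(array(3, dim = c(32, 32, 32)))
  g <- flat_grid(u = 4, v = 4, z0 = 30, origin = c(25, 25), step = 5)
  out <- resample_along_surface(vol, g, resample_spec(8, 2))
  data <- image_data(out)
  expect_false(any(!is.finite(data)))
  expect_true(any(!out$valid))        # some samples left the volume
  expect_equal(unique(as.vector(data[out$valid])), 3)
  expect_equal(unique(as.vector(data[!out$valid])), 3)  # fill = mean = 3
})

test_that("doubling step while halving the slab keeps the central slice", {
  vol <- sdist_volume()
  g <- flat_grid()
  a <- image_data(resample_along_surface(vol, g, resample_spec(10, 1)))
  b <- image_data(resample_along_surface(vol, g, resample_spec(10, 2)))
  expect_equal(a[(dim(a)[1] + 1) / 2, , ], b[(dim(b)[1] + 1) / 2, , ],
               tolerance = 1e-12)
})

test_that("project_mean equals the per-pixel loop oracle", {
  set.seed(3)
  vol <- image_volume(array(runif(512), dim = c(8, 8, 8)))
  for (axis in 1:3) {
    got <- image_data(project_mean(vol, axis))
    keep <- setdiff(1:3, axis)
    want <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      sel <- list(1:8, 1:8, 1:8)
      sel[[keep[1]]] <- i; sel[[keep[2]]] <- j
      want[i, j] <- mean(image_data(vol)[sel[[1]], sel[[2]], sel[[3]]])
    }
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
  expect_error(project_mean(vol, 5), class = "cryopick_argument_error")
})

test_that("projection ignores fill voxels when a validity mask exists", {
  vol <- image_volume(array(0, dim = c(32, 32, 32)))
  vol$data[, , 16] <- 10
  g <- flat_grid(u = 4, v = 4, z0 = 15, origin = c(25, 25), step = 5)
  out <- resample_along_surface(vol, g, resample_spec(4, 1))
  proj <- image_data(project_mean(out, 1))
  # in-bounds pixels: mean over 5 normal samples, exactly one of which (the
  # central slice) hits the bright plane
  fully_valid <- apply(out$valid, c(2, 3), all)
  expect_equal(unique(as.vector(proj[fully_valid])), 2)
})
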