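disk_mask <- function(n, centre, radius) {
  x <- seq_len(n) - 1
  outer((x - centre[1])^2, (x - centre[2])^2, "+") <= radius^2
}

equiv_radius <- function(mask) sqrt(sum(mask) / pi)

test_that("signed_distance_field matches the brute-force oracle", {
  m <- disk_mask(64, c(31, 31), 8) * 1
  sdf <- signed_distance_field(m)
  expect_equal(sdf[32, 32], 8, tolerance = 1)
  ora <- oracle_sdf(m)
  expect_lt(max(abs(sdf - ora)), 1e-9)
})

test_that("SDF conventions: empty/full masks, cap, and complement symmetry", {
  expect_equal(signed_distance_field(matrix(0, 8, 8)),
               array(-16, c(8, 8)))
  expect_equal(signed_distance_field(matrix(1, 8, 8)),
               array(16, c(8, 8)))
  m <- disk_mask(32, c(15, 15), 6) * 1
  a <- signed_distance_field(m)
  b <- signed_distance_field(1 - m)
  # negatives of each other up to the one-voxel boundary band
  expect_lt(max(abs(a + b)), 1.5)
  # cap honoured
  capped <- signed_distance_field(m, cap = 3)
  expect_lte(max(abs(capped)), 3)
  expect_error(signed_distance_field(matrix(0.5, 4, 4)),
               class = "cryopick_argument_error")
})

test_that("identical bounding disks interpolate to the same disk", {
  stack <- make_label_stack(size = c(48, 48, 11), slices = c(1, 11),
                            radii = c(6, 6))
  out <- interpolate_labels(stack, dim = 3)
  ref <- stack$data[, , 1]
  for (s in 2:10) {
    diffpix <- sum(out$data[, , s] != ref)
    # up to one voxel of boundary jitter
    expect_lt(diffpix, sum(ref) * 0.5)
    expect_lt(abs(equiv_radius(out$data[, , s] == 1) - 6), 1)
  }
})

test_that("concentric disks 4 -> 8 give radius 6 +/- 1 at the midpoint", {
  stack <- make_label_stack(size = c(64, 64, 11), slices = c(1, 11),
                            radii = c(4, 8))
  out <- interpolate_labels(stack, dim = 3)
  expect_equal(equiv_radius(out$data[, , 6] == 1), 6, tolerance = 1)
  # annotated slices preserved exactly
  expect_identical(out$data[, , 1], stack$data[, , 1])
  expect_identical(out$data[, , 11], stack$data[, , 11])
  # intermediate radii grow monotonically
  radii <- sapply(1:11, function(s) equiv_radius(out$data[, , s] == 1))
  expect_true(all(diff(radii) > -0.5))
})

test_that("two labels stay disjoint and match the per-label field oracle", {
  set.seed(19)
  for (rep in 1:6) {
    n <- 32
    c1 <- runif(2, 8, 12); r1 <- runif(2, 3, 6)
    c2 <- runif(2, 20, 24); h2 <- runif(2, 2, 5)
    stack <- array(0L, dim = c(n, n, 7))
    x <- seq_len(n) - 1
    for (k in 1:2) {
      s <- if (k == 1) 1 else 7
      disk <- outer((x - c1[k])^2, (x - c1[k])^2, "+") <= r1[k]^2
      sq <- outer(abs(x - c2[k]), abs(x - c2[k]), pmax) <= h2[k]
      slice <- matrix(0L, n, n)
      slice[disk] <- 1L
      slice[sq] <- 2L
      stack[, , s] <- slice
    }
    out <- interpolate_labels(labeled_volume(stack), dim = 3)
    for (s in 2:6) {
      got <- out$data[, , s]
      # oracle: per-label SDF average with max-field tie-break
      wa <- (7 - s) / 6; wb <- (s - 1) / 6
      fields <- lapply(1:2, function(id) {
        wa * oracle_sdf((stack[, , 1] == id) * 1) +
          wb * oracle_sdf((stack[, , 7] == id) * 1)
      })
      want <- matrix(0L, n, n)
      better <- fields[[2]] > fields[[1]]
      want[fields[[1]] > 0 & !better] <- 1L
      want[fields[[2]] > 0 & better] <- 2L
      expect_identical(got, want, label = sprintf("rep %d slice %d", rep, s))
    }
  }
})

test_that("interpolation needs two annotated slices and a valid axis", {
  one <- make_label_stack(size = c(16, 16, 5), slices = 2, radii = 3)
  expect_error(interpolate_labels(one, dim = 3),
               class = "cryopick_argument_error")
  two <- make_label_stack(size = c(16, 16, 5), slices = c(1, 5),
                          radii = c(3, 3))
  expect_error(interpolate_labels(two, dim = 7),
               class = "cryopick_argument_error")
})

test_that("slices outside the annotated range stay empty", {
  stack <- make_label_stack(size = c(32, 32, 12), slices = c(3, 9),
                            radii = c(4, 6))
  out <- interpolate_labels(stack, dim = 3)
  for (s in c(1, 2, 10, 11, 12)) expect_equal(sum(out$data[, , s]), 0)
  for (s in 4:8) expect_gt(sum(out$data[, , s]), 0)
})

test_that("interpolation commutes with reversal along the axis", {
  stack <- make_label_stack(size = c(32, 32, 9), slices = c(1, 9),
                            radii = c(3, 7))
  fwd <- interpolate_labels(stack, dim = 3)
  rev_in <- labeled_volume(stack$data[, , 9:1])
  rev_out <- interpolate_labels(rev_in, dim = 3)
  expect_identical(rev_out$data[, , 9:1], fwd$data)
})

test_that("monotone inclusion: nested masks stay nested after interpolation", {
  n <- 32
  x <- seq_len(n) - 1
  stack_big <- array(0L, dim = c(n, n, 7))
  stack_small <- array(0L, dim = c(n, n, 7))
  for (k in 1:2) {
    s <- if (k == 1) 1 else 7
    rb <- c(8, 12)[k]; rs <- c(4, 5)[k]
    stack_big[, , s] <- (outer((x - 15)^2, (x - 15)^2, "+") <= rb^2) * 1L
    stack_small[, , s] <- (outer((x - 15)^2, (x - 15)^2, "+") <= rs^2) * 1L
  }
  big <- interpolate_labels(labeled_volume(stack_big), dim = 3)
  small <- interpolate_labels(labeled_volume(stack_small), dim = 3)
  expect_true(all(big$data[small$data == 1L] == 1L))
})
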