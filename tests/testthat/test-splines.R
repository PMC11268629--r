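segment_spline <- function(len = 10, order = 3) {
  fit_spline3d(rbind(c(0, 0, 0), c(0, 0, len)), order)
}

circle_spline <- function(radius = 10, n = 32, order = 3) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  fit_spline3d(cbind(radius * cos(th), radius * sin(th), 0), order)
}

test_that("fit_spline3d interpolates, measures length, and demotes order", {
  sp <- segment_spline(10)
  expect_equal(spline_length(sp), 10, tolerance = 1e-6)
  expect_equal(unname(spline_position(sp, c(0, 1))),
               rbind(c(0, 0, 0), c(0, 0, 10)), tolerance = 1e-9)

  # full circle, length within 0.5% of 2*pi*r
  sp2 <- circle_spline(10, 32)
  expect_lt(abs(spline_length(sp2) - 2 * pi * 10), 0.005 * 2 * pi * 10)

  # 3 points with cubic request: demoted to degree 2, no error
  sp3 <- fit_spline3d(rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)), order = 3)
  expect_equal(sp3$degree, 2L)
  expect_equal(unname(spline_position(sp3, sp3$params[2])), rbind(c(1, 1, 0)),
               tolerance = 1e-8)

  expect_error(fit_spline3d(rbind(c(0, 0, 0))),
               class = "cryopick_argument_error")
  expect_error(fit_spline3d(rbind(c(1, 1, 1), c(1, 1, 1))),
               class = "cryopick_argument_error")
})

test_that("smoothing trades fidelity for smoothness but keeps the shape", {
  set.seed(5)
  t <- seq(0, 1, length.out = 20)
  noisy <- cbind(30 * t, 10 * sin(2 * pi * t), 0) + matrix(rnorm(60, sd = 0.4), 20)
  sp0 <- fit_spline3d(noisy, 3, smoothing = 0)
  sps <- fit_spline3d(noisy, 3, smoothing = 5)
  # interpolating spline passes through the data, smoothed one does not
  r0 <- max(abs(spline_position(sp0, sp0$params) - noisy))
  rs <- max(abs(spline_position(sps, sps$params) - noisy))
  expect_lt(r0, 1e-6)
  expect_gt(rs, r0)
  # but the smoothed curve stays near the data
  expect_lt(rs, 3)
})

test_that("sample_equidistant places samples at equal Euclidean spacing", {
  sp <- segment_spline(10)
  s <- sample_equidistant(sp, 2)
  expect_equal(unname(s$points[, 3]), c(0, 2, 4, 6, 8, 10), tolerance = 1e-6)
  expect_equal(unname(s$points[, 1:2]), matrix(0, 6, 2), tolerance = 1e-9)

  # spacing larger than the curve: the 2-endpoint minimum
  s2 <- sample_equidistant(sp, 100)
  expect_equal(nrow(s2$points), 2)
  expect_equal(unname(s2$points[2, ]), c(0, 0, 10), tolerance = 1e-6)

  # circle: relative spread of consecutive distances < 1e-3
  sc <- sample_equidistant(circle_spline(10), 1)
  d <- sqrt(rowSums(diff(sc$points)^2))
  expect_lt(sd(d) / mean(d), 1e-3)

  expect_error(sample_equidistant(sp, 0), class = "cryopick_argument_error")
  expect_error(sample_equidistant(sp, -1), class = "cryopick_argument_error")
})

test_that("arc-length table is monotone and resampling is stable under refit", {
  set.seed(13)
  for (rep in 1:5) {
    sp <- fit_spline3d(rand_smooth_points(8), 3)
    expect_true(all(diff(sp$arc_table$length) >= 0))
    s1 <- sample_equidistant(sp, 2)
    sp2 <- fit_spline3d(s1$points, 3)
    s2 <- sample_equidistant(sp2, 2)
    if (nrow(s1$points) == nrow(s2$points)) {
      expect_lt(max(abs(s1$points - s2$points)), 2 / 100)
    }
  }
})

test_that("frames_along yields proper twist-free frames with tangent local Z", {
  sp <- segment_spline(10)
  t <- seq(0, 1, length.out = 6)
  f <- frames_along(sp, t)
  expect_equal(f, array(diag(3), dim = c(3, 3, 6)), tolerance = 1e-9)

  # planar S-curve: frames rotate slowly and match a parallel-transport oracle
  tt <- seq(0, 1, length.out = 15)
  pts <- cbind(40 * tt, 10 * sin(2 * pi * tt), 0)
  sps <- fit_spline3d(pts, 3)
  tp <- seq(0, 1, length.out = 200)
  fr <- frames_along(sps, tp)
  for (i in seq_len(199)) {
    rel <- t(fr[, , i]) %*% fr[, , i + 1]
    ang <- acos(pmin(pmax((sum(diag(rel)) - 1) / 2, -1), 1)) * 180 / pi
    expect_lt(ang, 5)
  }
  for (i in c(1, 50, 200)) {
    expect_lt(abs(det(fr[, , i]) - 1), 1e-6)
    expect_lt(max(abs(crossprod(fr[, , i]) - diag(3))), 1e-6)
  }
  # local Z equals the unit tangent
  tan_raw <- spline_derivative(sps, tp)
  tan_unit <- tan_raw / sqrt(rowSums(tan_raw^2))
  expect_equal(t(fr[3, 3, ]), t(tan_unit[, 3]), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(fr[, 3, ] - t(tan_unit))), 1e-9)

  # independent minimal-rotation transport oracle
  pos <- spline_position(sps, tp)
  orc <- oracle_transport_frames(pos, tan_unit)
  expect_lt(max(abs(fr - orc)), 0.02)

  expect_error(frames_along(sp, c(-0.5)), class = "cryopick_argument_error")
})
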