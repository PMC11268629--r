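# Shared generators and independent oracles used across the suite.

# uniform random proper rotation via QR decomposition
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random pose set with a numeric feature column
rand_pose_set <- function(n, experiment_id = "tomo_1", pixel_spacing = 2) {
  ori <- array(0, dim = c(3, 3, n))
  for (i in seq_len(n)) ori[, , i] <- rand_rotation()
  pose_set(matrix(stats::runif(3 * n, 0, 200), n, 3), ori,
           data.frame(score = stats::runif(n)),
           experiment_id = experiment_id, pixel_spacing = pixel_spacing)
}

# smooth random 3D curve: a random-direction strand with gentle low-order
# Fourier undulations, so the curvature radius stays large against the
# sampling spacings used in the tests (the regime where equidistant arc
# samples are also equidistant in Euclidean space)
rand_smooth_points <- function(m = 8, span = 60) {
  t <- seq(0, 1, length.out = m)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  sapply(1:3, function(d) {
    a <- stats::rnorm(3, sd = c(2.5, 1.0, 0.4))
    span * dir[d] * t + a[1] * sin(pi * t) + a[2] * sin(2 * pi * t) +
      a[3] * cos(2 * pi * t)
  })
}

# independent parallel-transport frame oracle: rotate the previous normal by
# the minimal rotation taking tangent i onto tangent i+1
oracle_transport_frames <- function(positions, tangents) {
  k <- nrow(tangents)
  frames <- array(0, dim = c(3, 3, k))
  t0 <- tangents[1, ]
  axis <- diag(3)[, which.min(abs(t0))]
  r <- axis - sum(axis * t0) * t0
  r <- r / sqrt(sum(r^2))
  cross_o <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                              a[3] * b[1] - a[1] * b[3],
                              a[1] * b[2] - a[2] * b[1])
  frames[, , 1] <- cbind(r, cross_o(t0, r), t0)
  for (i in seq_len(k - 1)) {
    t1 <- tangents[i, ]; t2 <- tangents[i + 1, ]
    ax <- cross_o(t1, t2)
    s <- sqrt(sum(ax^2)); co <- sum(t1 * t2)
    if (s < 1e-12) {
      rn <- r
    } else {
      ax <- ax / s
      ang <- atan2(s, co)
      # Rodrigues rotation of r about ax by ang
      rn <- r * cos(ang) + cross_o(ax, r) * sin(ang) +
        ax * sum(ax * r) * (1 - cos(ang))
    }
    rn <- rn - sum(rn * t2) * t2
    rn <- rn / sqrt(sum(rn^2))
    frames[, , i + 1] <- cbind(rn, cross_o(t2, rn), t2)
    r <- rn
  }
  frames
}

# quadruple-loop convolution oracle with border clamping
oracle_convolve <- function(image, kernel) {
  n <- nrow(image); m <- ncol(image)
  ky <- nrow(kernel); kx <- ncol(kernel)
  ry <- (ky - 1) / 2; rx <- (kx - 1) / 2
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (a in 1:ky) for (b in 1:kx) {
      ii <- min(max(i + a - 1 - ry, 1), n)
      jj <- min(max(j + b - 1 - rx, 1), m)
      acc <- acc + kernel[a, b] * image[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# brute-force signed distance field: per-pixel min distance to the other set
oracle_sdf <- function(mask, cap = sum(dim(mask))) {
  idx <- which(mask == 1, arr.ind = TRUE)
  odx <- which(mask == 0, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (nrow(idx) == 0) return(matrix(-cap, nrow(mask), ncol(mask)))
  if (nrow(odx) == 0) return(matrix(cap, nrow(mask), ncol(mask)))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] == 1) {
      d <- sqrt(min((odx[, 1] - i)^2 + (odx[, 2] - j)^2))
      out[i, j] <- min(d, cap)
    } else {
      d <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
      out[i, j] <- max(-d, -cap)
    }
  }
  out
}

# independent exhaustive integer-shift alignment oracle (mean distance over
# index-matched overlap of >= 2, ties to smaller |shift| then smaller shift)
oracle_best_shift <- function(a, b) {
  candidates <- data.frame(o = integer(0), cost = numeric(0))
  for (o in (-(nrow(b) - 1)):(nrow(a) - 1)) {
    tot <- 0; cnt <- 0
    for (j in seq_len(nrow(b))) {
      ja <- j + o
      if (ja >= 1 && ja <= nrow(a)) {
        tot <- tot + sqrt(sum((b[j, ] - a[ja, ])^2))
        cnt <- cnt + 1
      }
    }
    if (cnt >= 2) {
      candidates <- rbind(candidates, data.frame(o = o, cost = tot / cnt))
    }
  }
  candidates <- candidates[order(candidates$cost, abs(candidates$o),
                                 candidates$o), ]
  candidates$o[1]
}

# angle in degrees between unit vectors
angle_deg <- function(a, b) {
  acos(pmin(pmax(abs(sum(a * b)), -1), 1)) * 180 / pi
}

expect_valid_poses <- function(poses) {
  expect_length(validate_poses(poses), 0)
}
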