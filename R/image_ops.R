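# CPU implementations of the visualisation-support maths: centred
# weighted-average convolution with border replication (the texture-sampling
# semantics of a GPU shader kernel), separable Gaussian filtering, FFT
# bandpass with raised-cosine edges, and power spectra.

#' Convolve a 2D image with a centred kernel
#'
#' Computes the centred weighted average
#' `out[i, j] = sum_{a, b} k[a, b] * img[i + a - cy, j + b - cx]`
#' (cross-correlation convention: the kernel is not flipped, so the impulse
#' response is the point-reflected kernel). Out-of-image samples replicate
#' the nearest border pixel, mimicking clamped texture sampling.
#'
#' @param image 2D numeric matrix.
#' @param kernel 2D numeric matrix with odd dimensions.
#' @return Matrix of the same shape as `image`.
#' @export
convolve2d <- function(image, kernel) {
  if (!is.matrix(image)) abort_argument("image must be a matrix")
  if (!is.matrix(kernel) || any(dim(kernel) %% 2 == 0)) {
    abort_argument("kernel dimensions must be odd (centred kernel)")
  }
  if (!all(is.finite(kernel))) abort_argument("kernel must be finite")
  n <- nrow(image); m <- ncol(image)
  ry <- (nrow(kernel) - 1) / 2
  rx <- (ncol(kernel) - 1) / 2
  out <- matrix(0, n, m)
  for (a in seq_len(nrow(kernel))) {
    ii <- pmin(pmax(seq_len(n) + (a - 1 - ry), 1), n)
    for (b in seq_len(ncol(kernel))) {
      jj <- pmin(pmax(seq_len(m) + (b - 1 - rx), 1), m)
      out <- out + kernel[a, b] * image[ii, jj]
    }
  }
  out
}

#' Sampled 1D/2D Gaussian kernels
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @param size Kernel width; `NULL` selects `2 * ceiling(3 * sigma) + 1`.
#' @return Numeric vector (`gaussian_kernel1d`) or matrix
#'   (`gaussian_kernel2d`), normalised to sum to 1.
#' @export
gaussian_kernel1d <- function(sigma, size = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort_argument("sigma must be positive")
  }
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) {
    abort_argument("kernel size must be a positive odd integer")
  }
  x <- seq_len(size) - 1 - (size - 1) / 2
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' @rdname gaussian_kernel1d
#' @export
gaussian_kernel2d <- function(sigma, size = NULL) {
  w <- gaussian_kernel1d(sigma, size)
  outer(w, w)
}

# one separable pass of taps `w` along `axis` of a 2D/3D array, clamped
conv1d_axis <- function(x, w, axis) {
  d <- dim(x)
  r <- (length(w) - 1) / 2
  out <- array(0, d)
  for (a in seq_along(w)) {
    idx <- pmin(pmax(seq_len(d[axis]) + (a - 1 - r), 1), d[axis])
    sel <- rep(list(quote(expr = )), length(d))
    sel[[axis]] <- idx
    shifted <- do.call(`[`, c(list(x), sel, list(drop = FALSE)))
    out <- out + w[a] * shifted
  }
  out
}

#' Separable Gaussian filter for 2D/3D images
#'
#' Applies the sampled 1D Gaussian along each axis in turn with
#' border-replication padding; mathematically identical to convolving with
#' the dense N-D Gaussian kernel under the same clamped sampling.
#'
#' @param image 2D or 3D numeric array.
#' @param sigma Standard deviation in pixels (> 0).
#' @param size Kernel width per axis; `NULL` = `2 * ceiling(3 * sigma) + 1`.
#' @return Filtered array of the same shape.
#' @export
gaussian_filter <- function(image, sigma, size = NULL) {
  if (!is.array(image) && !is.matrix(image)) {
    abort_argument("image must be a 2D or 3D array")
  }
  w <- gaussian_kernel1d(sigma, size)
  out <- image
  for (axis in seq_along(dim(image))) out <- conv1d_axis(out, w, axis)
  out
}

# signed frequency (cycles per image) along an axis of length n
freq_cycles <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k <= n / 2, k, k - n)
}

# array of radial frequency magnitudes (cycles/image) for dims `d`
radial_frequency <- function(d) {
  r2 <- array(0, d)
  tmpl <- array(0L, d)
  for (axis in seq_along(d)) {
    f2 <- freq_cycles(d[axis])^2
    r2 <- r2 + array(f2[slice.index(tmpl, axis)], d)
  }
  sqrt(r2)
}

#' Radial FFT bandpass filter
#'
#' Retains spatial frequencies with radial magnitude in
#' `[low, high]` cycles/image, with raised-cosine (smooth) transitions of
#' width `edge_width` frequency pixels around both cut-offs to limit
#' ringing. The DC component is removed whenever `low > 0`. Works on 2D and
#' 3D arrays; the output is real.
#'
#' @param image 2D or 3D numeric array.
#' @param low,high Band limits in cycles/image, `0 <= low < high`.
#' @param edge_width Soft-edge width in frequency pixels.
#' @return Filtered array of the same shape.
#' @export
bandpass_filter <- function(image, low, high, edge_width = 2) {
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || low >= high) {
    abort_argument("band limits must satisfy 0 <= low < high")
  }
  d <- dim(image)
  r <- radial_frequency(d)
  ramp <- function(r, cut, rising) {
    w <- edge_width
    t <- pmin(pmax((r - (cut - w / 2)) / w, 0), 1)
    s <- 0.5 * (1 - cos(pi * t))
    if (rising) s else 1 - s
  }
  mask <- ramp(r, low, TRUE) * ramp(r, high, FALSE)
  if (low > 0) mask[r == 0] <- 0
  ft <- stats::fft(image) * mask
  Re(stats::fft(ft, inverse = TRUE)) / length(image)
}

# reorder so the zero-frequency bin is centred along each axis
fftshift_array <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) ((seq_len(n) - 1 + ceiling(n / 2)) %% n) + 1)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Power spectrum of an image, volume, or stack
#'
#' Squared modulus of the unnormalised forward FFT with the zero-frequency
#' component shifted to the centre (so
#' `sum(power) == N_pixels * sum(image^2)`, Parseval's identity in this
#' convention). With `stack = TRUE` a 3D array is treated as a stack of 2D
#' images along its last axis and each member is processed independently.
#'
#' @param image 2D or 3D numeric array.
#' @param stack Treat the last axis as a stack dimension?
#' @return Array of the same shape containing the centred power.
#' @export
power_spectrum <- function(image, stack = FALSE) {
  if (!is.array(image) && !is.matrix(image)) {
    abort_argument("image must be a 2D or 3D array")
  }
  if (stack) {
    nd <- length(dim(image))
    out <- image
    for (k in seq_len(dim(image)[nd])) {
      sel <- c(rep(list(quote(expr = )), nd - 1), list(k))
      member <- do.call(`[`, c(list(image), sel, list(drop = TRUE)))
      res <- power_spectrum(member, stack = FALSE)
      out <- do.call(`[<-`, c(list(out), sel, list(res)))
    }
    return(out)
  }
  fftshift_array(Mod(stats::fft(image))^2)
}

#' Log display transform for power spectra
#'
#' @param power Non-negative array, e.g. from [power_spectrum()].
#' @return `log1p(power)`.
#' @export
log_power <- function(power) log1p(power)
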