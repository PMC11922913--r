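#' @keywords internal
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# reflect (symmetric, edge-repeating) index into 1..n
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# separable correlation with a symmetric 1-D kernel along rows then columns
separable_blur <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (t in seq_along(k)) {
    out <- out + k[t] * x[reflect_index(seq_len(n) + (t - 1L - r), n), , drop = FALSE]
  }
  x <- out
  out <- matrix(0, n, m)
  for (t in seq_along(k)) {
    out <- out + k[t] * x[, reflect_index(seq_len(m) + (t - 1L - r), m), drop = FALSE]
  }
  out
}

#' Gaussian low-pass filter
#'
#' Smooths the image by convolution with a normalized, separable Gaussian
#' kernel (truncated at three standard deviations), using reflected boundary
#' samples.  Because the kernel sums to one and the reflected extension makes
#' the operator doubly stochastic, a constant image is a fixed point and the
#' image mean is preserved.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param sigma positive Gaussian standard deviation in pixels.
#' @return a real-valued matrix of the same size (not quantized).
#' @export
low_pass <- function(img, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stopf("`sigma` must be a positive number")
  }
  x <- if (inherits(img, "gray_image")) {
    matrix(as.numeric(img), nrow(img), ncol(img))
  } else as.matrix(img) * 1.0
  separable_blur(x, gaussian_kernel_1d(sigma))
}

#' Gaussian high-pass filter
#'
#' The detail residual `img - low_pass(img, sigma)`: low-frequency content is
#' removed, leaving edges and fast intensity variations.  Output values may be
#' negative.
#'
#' @inheritParams low_pass
#' @return a signed real-valued matrix of the same size.
#' @export
high_pass <- function(img, sigma) {
  x <- if (inherits(img, "gray_image")) {
    matrix(as.numeric(img), nrow(img), ncol(img))
  } else as.matrix(img) * 1.0
  x - low_pass(x, sigma)
}

#' High-boost sharpening
#'
#' Computes `A * img - low_pass(img, sigma)` in real arithmetic — equivalently
#' `(A - 1) * img + high_pass(img, sigma)` — then clips to the representable
#' intensity range and rounds once at the end.  `A = 1` reduces to a clipped
#' high-pass filter; larger amplification factors retain more of the original
#' low-frequency content while sharpening edges.
#'
#' @inheritParams low_pass
#' @param A positive amplification factor.
#' @return a [gray_image()].
#' @export
high_boost <- function(img, A = 1.5, sigma = 1) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0) {
    stopf("`A` must be a positive number")
  }
  img <- as_gray_image(img)
  L <- levels_of(img)
  x <- matrix(as.numeric(img), nrow(img), ncol(img))
  hb <- A * x - low_pass(x, sigma)
  gray_image(pmin(pmax(round_half_up(hb), 0), L - 1), levels = L)
}
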