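#' Grayscale intensity image
#'
#' The substrate of all enhancement arithmetic: a matrix of integer pixel
#' intensities with an explicit number of representable levels (256 for 8-bit
#' mammograms).  Rows index the image's vertical axis, columns the horizontal
#' axis.
#'
#' @param pixels numeric matrix of intensities; values must be whole numbers in
#'   `[0, levels - 1]`.
#' @param levels number of intensity levels, default 256.
#' @return An object of class `gray_image`: an integer matrix carrying a
#'   `levels` attribute.
#' @examples
#' img <- gray_image(matrix(c(0, 0, 128, 255), 2, 2))
#' invert(img)
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stopf("image must have at least one row and one column")
  }
  if (!is_count(levels) || levels < 2L) stopf("`levels` must be an integer >= 2")
  if (anyNA(pixels)) stopf("image contains missing pixel values")
  if (any(pixels != floor(pixels))) stopf("pixel intensities must be whole numbers")
  if (any(pixels < 0) || any(pixels > levels - 1)) {
    stopf("pixel intensities must lie in [0, %d]", as.integer(levels) - 1L)
  }
  structure(matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
            levels = as.integer(levels),
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d levels>\n", nrow(x), ncol(x), levels_of(x)))
  invisible(x)
}

#' Number of intensity levels of an image
#'
#' @param img a [gray_image()] (a plain matrix is assumed to be 8-bit).
#' @return integer level count.
#' @export
levels_of <- function(img) as.integer(attr(img, "levels") %||% 256L)

#' Coerce to a grayscale image
#'
#' Matrices are validated as-is; 3-channel arrays are reduced to a single
#' luminance channel (Rec. 601 weights 0.299/0.587/0.114) before validation,
#' matching how color inputs are collapsed ahead of enhancement.
#'
#' @param x matrix or `height x width x 3` array, intensities in `[0, levels-1]`.
#' @param levels number of intensity levels.
#' @return a [gray_image()].
#' @export
as_gray_image <- function(x, levels = 256L) {
  if (inherits(x, "gray_image")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) {
      x <- x[, , 1L]
    } else if (dim(x)[3] >= 3L) {
      x <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
      x <- round_half_up(x)
    } else {
      stopf("cannot interpret a %d-channel array as grayscale", dim(x)[3])
    }
  }
  gray_image(as.matrix(x), levels = levels)
}

#' Read an 8-bit image file as a grayscale image
#'
#' PNG and JPEG are supported; RGB inputs are collapsed to luminance.
#'
#' @param path file path.
#' @return a [gray_image()] with 256 levels.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)              # (width, height[, channels]) in [0,1]
  a <- round_half_up(a * 255)
  if (length(dim(a)) == 2L) {
    m <- t(a)
  } else {
    m <- aperm(a[, , seq_len(dim(a)[3]), drop = FALSE], c(2, 1, 3))
    return(as_gray_image(m))
  }
  gray_image(m)
}

#' Write a grayscale image to disk
#'
#' @param img a [gray_image()] or matrix of intensities.
#' @param path output path; format follows the extension (`.png` or `.jpg`).
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  img <- as_gray_image(img)
  scaled <- unclass(img) / (levels_of(img) - 1)
  EBImage::writeImage(EBImage::Image(t(scaled)), path)
  invisible(path)
}

#' Invert image intensities
#'
#' Every pixel is replaced by `(levels - 1) - value`, so pure black (0) maps to
#' pure white (255 in an 8-bit image).  Inversion is its own inverse.
#'
#' @param img a [gray_image()] or intensity matrix.
#' @return the inverted [gray_image()].
#' @export
invert <- function(img) {
  img <- as_gray_image(img)
  gray_image((levels_of(img) - 1L) - unclass(img), levels = levels_of(img))
}
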