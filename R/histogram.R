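#' Intensity histogram of a grayscale image
#'
#' Tabulates per-level pixel counts H(k), the normalized frequencies
#' N(k) = H(k) / (n * m), and the cumulative distribution
#' CDF(j) = sum_{k <= j} N(k), the three quantities global histogram
#' equalization is built from.
#'
#' @param img a [gray_image()] or intensity matrix.
#' @return An object of class `intensity_histogram`: a list with `counts`,
#'   `normalized`, `cumulative` (each of length `levels`) and `levels`.
#' @examples
#' h <- compute_histogram(gray_image(matrix(c(0, 0, 128, 255), 2, 2)))
#' h$cumulative[129]  # CDF at level 128
#' @export
compute_histogram <- function(img) {
  img <- as_gray_image(img)
  L <- levels_of(img)
  counts <- tabulate(as.integer(img) + 1L, nbins = L)
  # cumulate the integer counts before normalizing: exact where summing the
  # per-level frequencies would accumulate rounding error at half-way points
  structure(list(counts = counts,
                 normalized = counts / length(img),
                 cumulative = cumsum(counts) / length(img),
                 levels = L),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  occ <- which(x$counts > 0L) - 1L
  cat(sprintf("<intensity_histogram: %d levels, %d occupied, %d pixels>\n",
              x$levels, length(occ), sum(x$counts)))
  invisible(x)
}

#' Histogram-equalization transfer map
#'
#' Builds the intensity look-up table P(x) = round((L - 1) * CDF(x)).  Halves
#' round upward so the table agrees digit-for-digit with a direct evaluation of
#' the remapping formula.  The map is monotone non-decreasing by construction
#' (the CDF is).
#'
#' @param hist an `intensity_histogram` (or a bare cumulative vector).
#' @param levels number of output levels; defaults to the histogram's.
#' @return An object of class `transfer_map`: an integer vector `lut` of length
#'   `levels`, where `lut[k + 1]` is the output level for input level `k`.
#' @export
equalization_map <- function(hist, levels = NULL) {
  cdf <- if (inherits(hist, "intensity_histogram")) hist$cumulative else as.numeric(hist)
  levels <- as.integer(levels %||%
    (if (inherits(hist, "intensity_histogram")) hist$levels else length(cdf)))
  lut <- as.integer(round_half_up((levels - 1L) * cdf))
  lut <- pmin(pmax(lut, 0L), levels - 1L)
  structure(list(lut = lut, levels = levels), class = "transfer_map")
}

#' @export
print.transfer_map <- function(x, ...) {
  cat(sprintf("<transfer_map: %d levels, range [%d, %d]>\n",
              x$levels, min(x$lut), max(x$lut)))
  invisible(x)
}

apply_map <- function(img, map) {
  img <- as_gray_image(img)
  gray_image(matrix(map$lut[as.integer(img) + 1L], nrow(img), ncol(img)),
             levels = map$levels)
}

#' Global histogram equalization
#'
#' Remaps every pixel through the image's own cumulative distribution so that
#' intensities spread across the representable range.  Pixel ordering is
#' preserved: a pixel at least as bright as another stays at least as bright.
#'
#' @param img a [gray_image()] or intensity matrix.
#' @return the equalized [gray_image()].
#' @examples
#' equalize(gray_image(matrix(c(0, 0, 128, 255), 2, 2)))
#' @export
equalize <- function(img) {
  img <- as_gray_image(img)
  apply_map(img, equalization_map(compute_histogram(img)))
}
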