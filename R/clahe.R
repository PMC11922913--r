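#' CLAHE configuration
#'
#' Parameters of contrast-limited adaptive histogram equalization: the tile
#' grid the image is partitioned into, the clip factor that caps local contrast
#' amplification, and the inter-tile interpolation scheme.
#'
#' The absolute clip limit for a tile is `clip_factor * tile_pixels / levels`,
#' i.e. a multiple of the mean histogram bin height; bins above the limit are
#' truncated and the excess mass is redistributed evenly over all bins, the
#' integer remainder one unit per bin starting at bin 0.
#'
#' @param tile_grid integer `(rows, cols)` of the tile partition, default `c(8, 8)`.
#' @param clip_factor positive multiple of the mean bin height, default 2.
#'   A factor at least `levels` never clips any bin.
#' @param interpolation `"bilinear"` (blend the four surrounding tile maps,
#'   the standard artifact-suppressing scheme) or `"none"` (each pixel uses its
#'   own tile's map; mainly for testing against a per-tile reference).
#' @return an object of class `clahe_config`.
#' @export
clahe_config <- function(tile_grid = c(8L, 8L), clip_factor = 2,
                         interpolation = c("bilinear", "none")) {
  interpolation <- match.arg(interpolation)
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || any(!is.finite(tile_grid)) || any(tile_grid < 1L)) {
    stopf("`tile_grid` must be two integers >= 1")
  }
  if (!is.numeric(clip_factor) || length(clip_factor) != 1L || clip_factor <= 0) {
    stopf("`clip_factor` must be a positive number")
  }
  structure(list(tile_grid = tile_grid, clip_factor = clip_factor,
                 interpolation = interpolation),
            class = "clahe_config")
}

# Clip a tile histogram at an integer ceiling and redistribute the excess:
# every bin gets floor(excess / L); the remainder is handed out one unit per
# bin starting at bin 0.  Total mass is conserved exactly.
clip_redistribute <- function(counts, clip_limit) {
  L <- length(counts)
  # a limit at or above the tile pixel count can never bind
  clip_limit <- max(1, min(floor(clip_limit), sum(counts)))
  excess <- sum(pmax(counts - clip_limit, 0L))
  clipped <- pmin(counts, clip_limit)
  clipped <- clipped + excess %/% L
  rem <- excess %% L
  if (rem > 0L) clipped[seq_len(rem)] <- clipped[seq_len(rem)] + 1L
  clipped
}

#' Contrast-limited adaptive histogram equalization
#'
#' Partitions the image into a grid of tiles, computes each tile's intensity
#' histogram, clips every bin at `clip_factor` times the mean bin height with
#' even redistribution of the clipped mass, builds the per-tile equalization
#' map from the clipped cumulative histogram, and maps each pixel by bilinear
#' interpolation between the maps of the four nearest tile centers (border
#' pixels fall back to the available two or one).  With a single tile and a
#' non-binding clip limit this reduces exactly to global [equalize()].
#'
#' @param img a [gray_image()] or intensity matrix, at least as large as the
#'   tile grid.
#' @param cfg a [clahe_config()].
#' @return the enhanced [gray_image()].
#' @examples
#' img <- gray_image(matrix(sample(0:255, 64, TRUE), 8, 8))
#' clahe(img, clahe_config(tile_grid = c(2, 2)))
#' @export
clahe <- function(img, cfg = clahe_config()) {
  img <- as_gray_image(img)
  if (!inherits(cfg, "clahe_config")) stopf("`cfg` must be a clahe_config")
  n <- nrow(img); m <- ncol(img); L <- levels_of(img)
  tr <- cfg$tile_grid[1]; tc <- cfg$tile_grid[2]
  if (tr > n || tc > m) {
    stopf("tile grid %dx%d exceeds image size %dx%d", tr, tc, n, m)
  }

  # contiguous tile partition with near-equal extents
  rb <- round(seq(0, n, length.out = tr + 1))
  cb <- round(seq(0, m, length.out = tc + 1))
  px <- unclass(img)

  luts <- array(0L, dim = c(L, tr, tc))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile <- px[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1], drop = FALSE]
      nt <- length(tile)
      counts <- tabulate(as.integer(tile) + 1L, nbins = L)
      clipped <- clip_redistribute(counts, cfg$clip_factor * nt / L)
      cdf <- cumsum(clipped) / nt
      luts[, i, j] <- equalization_map(cdf, levels = L)$lut
    }
  }

  pix1 <- as.integer(px) + 1L  # column-major over (row, col)

  if (cfg$interpolation == "none") {
    ti <- findInterval(seq_len(n), rb + 1L, rightmost.closed = FALSE)
    tj <- findInterval(seq_len(m), cb + 1L, rightmost.closed = FALSE)
    ti <- pmin(ti, tr); tj <- pmin(tj, tc)
    out <- luts[cbind(pix1, rep(ti, times = m), rep(tj, each = n))]
    return(gray_image(matrix(out, n, m), levels = L))
  }

  # bilinear blend between surrounding tile maps, clamped at the borders
  ctr_r <- (rb[-length(rb)] + rb[-1] + 1) / 2
  ctr_c <- (cb[-length(cb)] + cb[-1] + 1) / 2
  interp_axis <- function(coords, centers) {
    k <- length(centers)
    i0 <- findInterval(coords, centers)           # 0 .. k
    i1 <- pmin(i0 + 1L, k)
    i0c <- pmax(i0, 1L)
    w <- numeric(length(coords))
    inside <- i0 >= 1L & i0 < k
    if (any(inside)) {
      lo <- centers[i0c[inside]]; hi <- centers[i1[inside]]
      w[inside] <- (coords[inside] - lo) / (hi - lo)
    }
    w[i0 < 1L] <- 0   # above the first center: use it fully
    w[i0 >= k] <- 0   # below the last center: i0c == i1 == k
    list(lo = i0c, hi = i1, w = w)
  }
  ry <- interp_axis(seq_len(n), ctr_r)
  rx <- interp_axis(seq_len(m), ctr_c)

  iy0 <- rep(ry$lo, times = m); iy1 <- rep(ry$hi, times = m)
  wy  <- rep(ry$w,  times = m)
  ix0 <- rep(rx$lo, each = n); ix1 <- rep(rx$hi, each = n)
  wx  <- rep(rx$w,  each = n)

  v00 <- luts[cbind(pix1, iy0, ix0)]
  v01 <- luts[cbind(pix1, iy0, ix1)]
  v10 <- luts[cbind(pix1, iy1, ix0)]
  v11 <- luts[cbind(pix1, iy1, ix1)]
  val <- (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
  gray_image(matrix(pmin(pmax(round_half_up(val), 0), L - 1), n, m), levels = L)
}
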