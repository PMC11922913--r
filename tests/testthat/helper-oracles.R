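# Independent reference implementations used as oracles.  These are written
# as direct, slow evaluations of the defining formulas, deliberately sharing
# no code with the package internals they check.

# strip class and the levels attribute, keep dimensions
plain_mat <- function(img) {
  m <- unclass(img)
  attributes(m) <- attributes(m)["dim"]
  m
}

# histogram equalization by per-pixel evaluation of
# N(k) = H(k)/(n*m);  CDF(j) = sum_{k<=j} N(k);  P = round((L-1) * CDF(x))
oracle_equalize <- function(m, levels = 256L) {
  n <- length(m)
  cdf <- function(j) sum(m <= j) / n
  out <- m
  for (i in seq_along(m)) {
    out[i] <- floor((levels - 1) * cdf(m[i]) + 0.5)
  }
  storage.mode(out) <- "integer"
  out
}

# per-tile CLAHE without interpolation: each tile equalized in isolation on
# its clipped histogram
oracle_clahe_tiles <- function(m, tile_rows, tile_cols, clip_factor, levels = 256L) {
  rb <- round(seq(0, nrow(m), length.out = tile_rows + 1))
  cb <- round(seq(0, ncol(m), length.out = tile_cols + 1))
  out <- m
  for (i in seq_len(tile_rows)) {
    for (j in seq_len(tile_cols)) {
      rows <- (rb[i] + 1):rb[i + 1]; cols <- (cb[j] + 1):cb[j + 1]
      tile <- m[rows, cols, drop = FALSE]
      counts <- vapply(0:(levels - 1), function(k) sum(tile == k), numeric(1))
      limit <- max(1, floor(clip_factor * length(tile) / levels))
      excess <- sum(pmax(counts - limit, 0))
      counts <- pmin(counts, limit) + excess %/% levels
      rem <- excess %% levels
      if (rem > 0) counts[1:rem] <- counts[1:rem] + 1
      cdf <- cumsum(counts) / length(tile)
      lut <- floor((levels - 1) * cdf + 0.5)
      out[rows, cols] <- matrix(lut[tile + 1], length(rows), length(cols))
    }
  }
  storage.mode(out) <- "integer"
  out
}

# reflect (symmetric) index used by the blur oracle
oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# direct 2-D convolution of a matrix with an arbitrary kernel, reflected edges
oracle_conv_reflect <- function(m, kern) {
  r <- (nrow(kern) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (y in seq_len(nrow(m))) {
    for (x in seq_len(ncol(m))) {
      acc <- 0
      for (dy in -r:r) {
        for (dx in -r:r) {
          acc <- acc + kern[dy + r + 1, dx + r + 1] *
            m[oracle_reflect(y + dy, nrow(m)), oracle_reflect(x + dx, ncol(m))]
        }
      }
      out[y, x] <- acc
    }
  }
  out
}

oracle_gauss_kernel2d <- function(sigma) {
  r <- max(1, ceiling(3 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  outer(k1, k1)
}

# brute-force multi-channel valid/same convolution, zero padding
# x: (H, W, Cin); W: (kh, kw, Cin, Cout)
oracle_conv2d <- function(x, W, b, pad) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  xp <- array(0, c(H + 2 * pad, Wd + 2 * pad, Cin))
  xp[pad + seq_len(H), pad + seq_len(Wd), ] <- x
  Ho <- H + 2 * pad - kh + 1; Wo <- Wd + 2 * pad - kw + 1
  out <- array(0, c(Ho, Wo, Cout))
  for (o in seq_len(Cout)) {
    for (i in seq_len(Ho)) {
      for (j in seq_len(Wo)) {
        acc <- b[o]
        for (c in seq_len(Cin)) {
          for (di in seq_len(kh)) {
            for (dj in seq_len(kw)) {
              acc <- acc + xp[i + di - 1, j + dj - 1, c] * W[di, dj, c, o]
            }
          }
        }
        out[i, j, o] <- acc
      }
    }
  }
  out
}

random_gray <- function(nr, nc, n_levels = 256, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lv <- sort(sample(0:255, n_levels))
  gray_image(matrix(sample(lv, nr * nc, replace = TRUE), nr, nc))
}

# rank-based AUC of score separating labels (1 = positive), ties counted half
rank_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
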