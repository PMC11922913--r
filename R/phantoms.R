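#' Synthetic mammogram phantom configuration
#'
#' Parameters of the seeded phantom generator.  Phantoms emulate the gross
#' structure of screening mammograms — an elliptical breast region filled with
#' smoothed fibroglandular texture — with a single bright lesion whose
#' morphology encodes the class: benign lesions are radially smooth,
#' near-circular blobs; malignant lesions are star-shaped masses with
#' radiating spicules and a perturbed boundary.  Both classes draw their base
#' radius from the same range, so boundary shape (not size) carries the class
#' signal.
#'
#' @param image_size square image side in pixels (>= 32), default 128.
#' @param n_benign,n_malignant images per class for [generate_dataset()].
#' @param benign_radius_range base lesion radius range in pixels (both classes).
#' @param spicule_count_range integer range of spicule counts for malignant
#'   lesions.
#' @param irregularity boundary perturbation amplitude in `[0, 1]`; 0 makes
#'   malignant boundaries as smooth as benign ones.
#' @param background_texture_scale Gaussian blur width (pixels) of the
#'   fibroglandular noise field.
#' @param noise_sigma additive Gaussian pixel noise level (intensity levels).
#' @param contrast lesion-to-background intensity gap in levels.
#' @param seed master seed; all generator randomness derives from it.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L, n_benign = 100L, n_malignant = 100L,
                           benign_radius_range = c(12, 20),
                           spicule_count_range = c(5L, 12L),
                           irregularity = 0.35,
                           background_texture_scale = 8,
                           noise_sigma = 8,
                           contrast = 70,
                           seed = 1L) {
  if (!is_count(image_size) || image_size < 32L) stopf("`image_size` must be an integer >= 32")
  if (!is_count(n_benign) || !is_count(n_malignant) || n_benign < 0 || n_malignant < 0) {
    stopf("class counts must be non-negative integers")
  }
  if (irregularity < 0 || irregularity > 1) stopf("`irregularity` must be in [0, 1]")
  structure(list(image_size = as.integer(image_size),
                 n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 benign_radius_range = benign_radius_range,
                 spicule_count_range = as.integer(spicule_count_range),
                 irregularity = irregularity,
                 background_texture_scale = background_texture_scale,
                 noise_sigma = noise_sigma,
                 contrast = contrast,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Generate a single synthetic phantom
#'
#' Builds one image as: elliptical breast mask x smoothed-noise texture +
#' lesion + additive noise, clipped to `[0, 255]`.  The lesion's radial
#' boundary is `r` for benign phantoms and
#' `r * (1 + irregularity * cos(k * theta + phase))` for malignant phantoms
#' with `k` spicules.  Fully deterministic for a fixed `(cfg, label, seed)`.
#'
#' @param cfg a [phantom_config()].
#' @param label `"benign"` or `"malignant"`.
#' @param seed integer seed for this phantom.
#' @return An object of class `phantom_image`: list with `image` (a
#'   [gray_image()]), `label`, and `truth` (lesion center, base radius,
#'   spicule count, and boundary roughness — the radial standard deviation of
#'   the boundary divided by its mean).
#' @export
generate_phantom <- function(cfg = phantom_config(), label = c("benign", "malignant"),
                             seed = 1L) {
  label <- match.arg(label)
  s <- cfg$image_size
  with_seed(seed, {
    ax <- s * stats::runif(1, 0.36, 0.44)       # ellipse semi-axes
    ay <- s * stats::runif(1, 0.40, 0.48)
    cx0 <- (s + 1) / 2; cy0 <- (s + 1) / 2
    ys <- matrix(rep(seq_len(s), times = s), s, s) - cy0
    xs <- matrix(rep(seq_len(s), each = s), s, s) - cx0
    edist <- sqrt((xs / ax)^2 + (ys / ay)^2)
    mask <- smoothstep((1 - edist) / 0.08)

    texture <- separable_blur(matrix(stats::rnorm(s * s), s, s),
                              gaussian_kernel_1d(cfg$background_texture_scale))
    texture <- texture / max(stats::sd(texture), 1e-12) * 18
    background <- (95 + texture) * mask

    # lesion center well inside the breast region
    repeat {
      lx <- stats::runif(1, -0.45, 0.45) * ax
      ly <- stats::runif(1, -0.45, 0.45) * ay
      if ((lx / ax)^2 + (ly / ay)^2 < 0.45^2) break
    }
    r <- stats::runif(1, cfg$benign_radius_range[1], cfg$benign_radius_range[2])
    k <- if (label == "malignant") {
      sample(cfg$spicule_count_range[1]:cfg$spicule_count_range[2], 1)
    } else 0L
    phase <- stats::runif(1, 0, 2 * pi)

    dx <- xs - lx; dy <- ys - ly
    d <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    rb <- if (label == "malignant") {
      r * (1 + cfg$irregularity * cos(k * theta + phase))
    } else {
      matrix(r, s, s)
    }
    core <- exp(-0.5 * (d / (0.7 * pmax(rb, 1e-9)))^2)
    edge <- smoothstep((rb - d) / (0.18 * r))
    lesion <- cfg$contrast * (0.35 * core + 0.65 * edge) * mask

    noise <- matrix(stats::rnorm(s * s, sd = cfg$noise_sigma), s, s) * mask
    img <- pmin(pmax(round_half_up(background + lesion + noise), 0), 255)

    thetas <- seq(0, 2 * pi, length.out = 361)[-361]
    radial <- if (label == "malignant") {
      r * (1 + cfg$irregularity * cos(k * thetas + phase))
    } else rep(r, length(thetas))
    structure(list(image = gray_image(img),
                   label = label,
                   truth = list(center = c(x = lx + cx0, y = ly + cy0),
                                radius = r,
                                spicules = k,
                                roughness = stats::sd(radial) / mean(radial))),
              class = "phantom_image")
  })
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image: %s, radius %.1f px, %d spicules, roughness %.3f>\n",
              x$label, x$truth$radius, x$truth$spicules, x$truth$roughness))
  invisible(x)
}

#' Generate a labeled phantom dataset
#'
#' Generates exactly the configured number of benign and malignant phantoms,
#' each with its own seed derived from the master seed.  With
#' `imbalance = "paper"` the benign:malignant ratio is reset to the clinical
#' archive proportions 6,200:1,005 (nearest integer at the requested total),
#' reflecting the dominance of screening-detected benign images.  If `dir` is
#' given, images are written as PNGs under `benign/` and `malignant/`
#' subfolders (loadable by [load_dataset()]) together with `manifest.csv` and
#' a `truth.csv` sidecar of ground-truth lesion parameters.
#'
#' @param cfg a [phantom_config()].
#' @param dir optional output directory.
#' @param imbalance `"none"` (use the configured counts) or `"paper"`.
#' @return a `labeled_dataset` with a `truth` data.frame attached.
#' @export
generate_dataset <- function(cfg = phantom_config(), dir = NULL,
                             imbalance = c("none", "paper")) {
  imbalance <- match.arg(imbalance)
  nb <- cfg$n_benign; nm <- cfg$n_malignant
  if (nb + nm < 1L) stopf("requested dataset is empty (n_benign + n_malignant = 0)")
  if (imbalance == "paper") {
    total <- nb + nm
    nb <- as.integer(round(total * 6200 / 7205))
    nm <- total - nb
  }
  labels <- rep(c("benign", "malignant"), c(nb, nm))
  n <- length(labels)
  images <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(cfg, labels[i],
                           seed = (cfg$seed + 104729 * i) %% .Machine$integer.max)
    images[[i]] <- ph$image
    truth[[i]] <- data.frame(id = sprintf("%s/phantom_%04d.png", labels[i], i),
                             label = labels[i],
                             center_x = ph$truth$center[["x"]],
                             center_y = ph$truth$center[["y"]],
                             radius = ph$truth$radius,
                             spicules = ph$truth$spicules,
                             roughness = ph$truth$roughness,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  items <- data.frame(id = truth$id, path = truth$id,
                      label = as.integer(labels == "malignant"),
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    for (cls in unique(labels)) {
      dir.create(file.path(dir, cls), recursive = TRUE, showWarnings = FALSE)
    }
    for (i in seq_len(n)) {
      write_gray(images[[i]], file.path(dir, truth$id[i]))
    }
    items$path <- file.path(dir, truth$id)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(data.frame(path = truth$id, label = labels),
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  new_labeled_dataset(items, images, truth)
}
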