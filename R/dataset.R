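#' Labeled mammogram dataset
#'
#' A collection of grayscale images with binary labels (0 = benign,
#' 1 = malignant), loaded either from a two-class folder tree
#' (`benign/`, `malignant/`) or from a CSV manifest with `path,label` columns.
#'
#' @param root_dir directory containing `benign/` and `malignant/` subfolders
#'   of PNG/JPEG images, or the path of a CSV manifest.
#' @param load read the images into memory (default); unreadable files are
#'   skipped with a warning reporting how many.
#' @return An object of class `labeled_dataset`: a list with `items` (a
#'   data.frame of `id`, `path`, `label`), `images` (list of [gray_image()]s,
#'   parallel to `items`) and `class_counts` (named counts for labels 0 and 1).
#' @export
load_dataset <- function(root_dir, load = TRUE) {
  if (length(root_dir) != 1L || !is.character(root_dir)) {
    stopf("`root_dir` must be a single path")
  }
  if (dir.exists(root_dir)) {
    items <- NULL
    for (cls in c("benign", "malignant")) {
      sub <- file.path(root_dir, cls)
      if (!dir.exists(sub)) next
      files <- list.files(sub, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                          full.names = TRUE)
      if (length(files)) {
        items <- rbind(items, data.frame(
          id = file.path(cls, basename(files)),
          path = files,
          label = if (cls == "malignant") 1L else 0L,
          stringsAsFactors = FALSE))
      }
    }
    if (is.null(items) || !nrow(items)) {
      stopf("no readable images found under %s (expected benign/ and malignant/ subfolders)",
            root_dir)
    }
  } else if (file.exists(root_dir)) {
    man <- utils::read.csv(root_dir, stringsAsFactors = FALSE)
    if (!all(c("path", "label") %in% names(man))) {
      stopf("manifest must have `path` and `label` columns")
    }
    lab <- tolower(as.character(man$label))
    bad <- setdiff(unique(lab), c("benign", "malignant", "0", "1"))
    if (length(bad)) stopf("unknown label value in manifest: %s", bad[1])
    paths <- ifelse(file.exists(man$path), man$path,
                    file.path(dirname(root_dir), man$path))
    items <- data.frame(id = man$path, path = paths,
                        label = ifelse(lab %in% c("malignant", "1"), 1L, 0L),
                        stringsAsFactors = FALSE)
    if (anyDuplicated(items$id)) {
      stopf("duplicate identifier in manifest: %s", items$id[duplicated(items$id)][1])
    }
    if (!nrow(items)) stopf("manifest lists no images")
  } else {
    stopf("no such directory or manifest: %s", root_dir)
  }

  images <- NULL
  if (load) {
    images <- vector("list", nrow(items))
    ok <- logical(nrow(items))
    for (i in seq_len(nrow(items))) {
      img <- tryCatch(read_gray(items$path[i]), error = function(e) NULL)
      if (!is.null(img)) { images[[i]] <- img; ok[i] <- TRUE }
    }
    if (!any(ok)) stopf("no readable images found under %s", root_dir)
    if (any(!ok)) {
      warning(sprintf("skipped %d unreadable image file(s)", sum(!ok)), call. = FALSE)
      items <- items[ok, , drop = FALSE]
      images <- images[ok]
    }
  }
  new_labeled_dataset(items, images)
}

new_labeled_dataset <- function(items, images = NULL, truth = NULL) {
  rownames(items) <- NULL
  structure(list(items = items, images = images,
                 class_counts = c(`0` = sum(items$label == 0L),
                                  `1` = sum(items$label == 1L)),
                 truth = truth),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d images (%d benign, %d malignant)%s>\n",
              nrow(x$items), x$class_counts[["0"]], x$class_counts[["1"]],
              if (is.null(x$images)) ", not loaded" else ""))
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) nrow(x$items)

subset_dataset <- function(ds, idx) {
  new_labeled_dataset(ds$items[idx, , drop = FALSE],
                      if (!is.null(ds$images)) ds$images[idx],
                      if (!is.null(ds$truth)) ds$truth[idx, , drop = FALSE])
}

#' Train/validation/test split configuration
#'
#' @param fractions `(train, validation, test)` fractions summing to 1,
#'   default `c(0.8, 0.1, 0.1)`.
#' @param seed integer seed making the split reproducible.
#' @param stratified apply the size rule within each class, default `TRUE`.
#' @return an object of class `split_config`.
#' @export
split_config <- function(fractions = c(0.8, 0.1, 0.1), seed = 1L, stratified = TRUE) {
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1)) {
    stopf("`fractions` must be three values in (0, 1)")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stopf("`fractions` must sum to 1")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_config")
}

split_indices <- function(n, fractions, perm) {
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test        # rounding remainder goes to train
  list(train = perm[seq_len(n_train)],
       val = if (n_val) perm[n_train + seq_len(n_val)] else integer(0),
       test = if (n_test) perm[n_train + n_val + seq_len(n_test)] else integer(0))
}

#' Split a dataset into train/validation/test partitions
#'
#' Partition sizes follow `round(fraction * n)` for the validation and test
#' sets with the remainder assigned to training; in stratified mode (the
#' default) the rule is applied per class so each partition preserves the
#' class ratio to within one image.  The partition is disjoint, exhaustive and
#' deterministic for a fixed seed.
#'
#' @param ds a [load_dataset()] / [generate_dataset()] dataset.
#' @param cfg a [split_config()].
#' @return named list of `labeled_dataset`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(ds, cfg = split_config()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  n <- nrow(ds$items)
  if (!n) stopf("cannot split an empty dataset")
  stratified <- cfg$stratified
  if (stratified && any(table(ds$items$label) < 3L)) {
    warning("a class has fewer items than partitions; falling back to an unstratified split",
            call. = FALSE)
    stratified <- FALSE
  }
  idx <- with_seed(cfg$seed, {
    if (stratified) {
      parts <- list(train = integer(0), val = integer(0), test = integer(0))
      for (cls in c(0L, 1L)) {
        who <- which(ds$items$label == cls)
        if (!length(who)) next
        sp <- split_indices(length(who), cfg$fractions, sample(length(who)))
        for (p in names(parts)) parts[[p]] <- c(parts[[p]], who[sp[[p]]])
      }
      parts
    } else {
      split_indices(n, cfg$fractions, sample(n))
    }
  })
  lapply(idx, function(i) subset_dataset(ds, sort(i)))
}

resize_bilinear <- function(mat, target) {
  if (nrow(mat) == target && ncol(mat) == target) return(mat)
  im <- EBImage::resize(EBImage::Image(t(mat)), w = target, h = target,
                        filter = "bilinear")
  t(EBImage::imageData(im))
}

# one image (gray_image / matrix / HxWx3 array) -> (target, target, 3) in [0,1]
preprocess_one <- function(img, target_size) {
  if (inherits(img, "gray_image")) {
    m <- matrix(as.numeric(img), nrow(img), ncol(img)) / (levels_of(img) - 1)
    m <- resize_bilinear(m, target_size)
    return(array(m, c(target_size, target_size, 3L)))
  }
  if (is.matrix(img)) {
    if (anyNA(img) || min(img) < 0) stopf("invalid image intensities")
    if (is.double(img) && max(img) <= 1) {
      m <- img
    } else if (all(img == floor(img)) && max(img) <= 255) {
      m <- img / 255
    } else {
      stopf("images must be 8-bit (integers in [0, 255]) or already normalized to [0, 1]")
    }
    m <- resize_bilinear(m, target_size)
    return(array(m, c(target_size, target_size, 3L)))
  }
  if (is.array(img) && length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    if (anyNA(img) || min(img) < 0) stopf("invalid image intensities")
    if (is.double(img) && max(img) <= 1) {
      a <- img
    } else if (all(img == floor(img)) && max(img) <= 255) {
      a <- img / 255
    } else {
      stopf("images must be 8-bit (integers in [0, 255]) or already normalized to [0, 1]")
    }
    out <- array(0, c(target_size, target_size, 3L))
    for (c3 in 1:3) {
      out[, , c3] <- resize_bilinear(a[, , min(c3, ch)], target_size)
    }
    return(out)
  }
  stopf("cannot preprocess object of class %s", class(img)[1])
}

#' Preprocess images into a normalized model-ready batch
#'
#' Each image is resized to `target_size x target_size` (bilinear), grayscale
#' content is replicated to 3 channels, and 8-bit intensities are divided by
#' 255 so every value lies in `[0, 1]`.  Inputs that are already normalized
#' and already at the target size pass through unchanged, so the operation is
#' idempotent.
#'
#' @param images a `labeled_dataset`, a list of images, or a single image
#'   ([gray_image()], matrix, or `H x W x C` array).
#' @param target_size output side length in pixels, default 128.
#' @return array shaped `(n, target_size, target_size, 3)` with values in
#'   `[0, 1]`.
#' @export
preprocess_batch <- function(images, target_size = 128L) {
  if (!is_count(target_size) || target_size < 1) stopf("`target_size` must be a positive integer")
  if (inherits(images, "labeled_dataset")) {
    if (is.null(images$images)) stopf("dataset was loaded without images")
    images <- images$images
  }
  if (!is.list(images)) images <- list(images)
  n <- length(images)
  out <- array(0, c(n, target_size, target_size, 3L))
  for (i in seq_len(n)) out[i, , , ] <- preprocess_one(images[[i]], target_size)
  out
}

rotate_bilinear <- function(m, angle_deg) {
  n <- nrow(m); w <- ncol(m)
  th <- angle_deg * pi / 180
  cy <- (n + 1) / 2; cx <- (w + 1) / 2
  ys <- rep(seq_len(n), times = w) - cy
  xs <- rep(seq_len(w), each = n) - cx
  # inverse rotation of output coordinates into the source image
  sy <- cos(th) * ys - sin(th) * xs + cy
  sx <- sin(th) * ys + cos(th) * xs + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  at <- function(yy, xx) {
    ok <- yy >= 1 & yy <= n & xx >= 1 & xx <= w
    v <- numeric(length(yy))
    v[ok] <- m[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - fy) * (1 - fx) * at(y0, x0) + (1 - fy) * fx * at(y0, x0 + 1) +
    fy * (1 - fx) * at(y0 + 1, x0) + fy * fx * at(y0 + 1, x0 + 1)
  matrix(v, n, w)
}

#' Label-preserving augmentation
#'
#' Applies a horizontal flip with probability 0.5 and a rotation drawn
#' uniformly from +/- 10 degrees (bilinear resampling about the image center,
#' zero fill outside), deterministic for a fixed seed.  Output shape equals
#' input shape.
#'
#' @param image normalized image: matrix or `H x W x C` array with values in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @param flip,angle optional overrides forcing the flip decision and rotation
#'   angle (used mainly in tests).
#' @return augmented image with the same dimensions.
#' @export
augment_image <- function(image, seed = NULL, flip = NULL, angle = NULL) {
  with_seed(seed, {
    do_flip <- flip %||% (stats::runif(1) < 0.5)
    theta <- angle %||% stats::runif(1, -10, 10)
    one <- function(m) {
      if (do_flip) m <- m[, ncol(m):1, drop = FALSE]
      if (abs(theta) > 1e-12) m <- rotate_bilinear(m, theta)
      m
    }
    if (is.matrix(image)) return(one(image))
    if (is.array(image) && length(dim(image)) == 3L) {
      out <- image
      for (c3 in seq_len(dim(image)[3])) out[, , c3] <- one(image[, , c3])
      return(out)
    }
    stopf("`image` must be a matrix or H x W x C array")
  })
}
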