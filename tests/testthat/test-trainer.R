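make_tree <- function(n_benign, n_malignant, size = 24, seed = 1) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  set.seed(seed)
  for (cls in c("benign", "malignant")) {
    n <- if (cls == "benign") n_benign else n_malignant
    if (n > 0) dir.create(file.path(root, cls), recursive = TRUE)
    for (i in seq_len(n)) {
      img <- gray_image(matrix(sample(0:255, size * size, TRUE), size, size))
      write_gray(img, file.path(root, cls, sprintf("%s_%02d.png", cls, i)))
    }
  }
  root
}

test_that("folder trees load with per-class counts and bad inputs are fatal", {
  root <- make_tree(3, 2)
  ds <- load_dataset(root)
  expect_length(ds, 5)
  expect_equal(unname(ds$class_counts), c(3L, 2L))
  expect_true(all(vapply(ds$images, inherits, logical(1), "gray_image")))

  empty <- withr::local_tempdir()
  expect_error(load_dataset(empty), "no readable images")

  # a corrupt file is skipped with a warning, not a failure
  writeLines("not a png", file.path(root, "benign", "broken.png"))
  expect_warning(ds2 <- load_dataset(root), "skipped 1")
  expect_length(ds2, 5)
})

test_that("CSV manifests load and reject duplicates and unknown labels", {
  root <- make_tree(2, 1)
  files <- list.files(root, recursive = TRUE, pattern = "png$")
  man <- file.path(root, "manifest.csv")
  utils::write.csv(data.frame(path = files,
                              label = ifelse(grepl("malignant", files),
                                             "malignant", "benign")),
                   man, row.names = FALSE)
  ds <- load_dataset(man)
  expect_length(ds, 3)
  expect_equal(unname(ds$class_counts), c(2L, 1L))

  utils::write.csv(data.frame(path = rep(files[1], 2), label = "benign"),
                   man, row.names = FALSE)
  expect_error(load_dataset(man), "duplicate")

  utils::write.csv(data.frame(path = files[1], label = "weird"),
                   man, row.names = FALSE)
  expect_error(load_dataset(man), "weird")
})

fake_ds <- function(labels) {
  items <- data.frame(id = sprintf("img%03d", seq_along(labels)),
                      path = sprintf("img%03d", seq_along(labels)),
                      label = labels)
  rdnet:::new_labeled_dataset(items,
                              replicate(length(labels),
                                        gray_image(matrix(0L, 4, 4)),
                                        simplify = FALSE))
}

test_that("splits hit the 80/10/10 protocol sizes and are disjoint and reproducible", {
  ds <- fake_ds(rep(c(0L, 1L), each = 50))
  parts <- split_dataset(ds, split_config(seed = 3))
  expect_equal(unname(vapply(parts, length, integer(1))), c(80L, 10L, 10L))

  ids <- unlist(lapply(parts, function(p) p$items$id))
  expect_length(ids, 100)
  expect_false(anyDuplicated(ids) > 0)

  small <- split_dataset(fake_ds(rep(c(0L, 1L), each = 5)),
                         split_config(seed = 1, stratified = FALSE))
  expect_equal(unname(vapply(small, length, integer(1))), c(8L, 1L, 1L))

  # stratification keeps a 60:40 ratio within one image per partition
  strat <- split_dataset(fake_ds(rep(c(0L, 1L), c(60, 40))), split_config(seed = 9))
  for (p in strat) {
    expect_lte(abs(sum(p$items$label == 0) - 0.6 * length(p)), 1)
  }

  again <- split_dataset(ds, split_config(seed = 3))
  expect_identical(lapply(again, function(p) p$items$id),
                   lapply(parts, function(p) p$items$id))
  other <- split_dataset(ds, split_config(seed = 4))
  expect_false(identical(other$test$items$id, parts$test$items$id))
})

test_that("a class smaller than the partition count degrades to an unstratified split", {
  ds <- fake_ds(c(rep(0L, 10), 1L, 1L))
  expect_warning(parts <- split_dataset(ds, split_config(seed = 1)), "unstratified")
  expect_equal(sum(vapply(parts, length, integer(1))), 12L)
})

test_that("preprocessing normalizes, resizes, replicates channels, and is idempotent", {
  img <- gray_image(matrix(c(0L, 255L, 128L, 64L), 2, 2))
  x <- preprocess_batch(list(img), target_size = 2)
  expect_equal(dim(x), c(1, 2, 2, 3))
  expect_equal(x[1, 1, 1, 1], 0)
  expect_equal(x[1, 2, 1, 1], 1)           # 255 -> 1.0
  expect_equal(x[1, 1, 2, 2], 128 / 255)
  expect_identical(x[1, , , 1], x[1, , , 3])

  big <- gray_image(matrix(sample(0:255, 72 * 72, TRUE), 72, 72))
  y <- preprocess_batch(list(big), target_size = 16)
  expect_equal(dim(y), c(1, 16, 16, 3))
  expect_true(all(y >= 0 & y <= 1))

  # already-normalized, already-sized input passes through unchanged
  z <- preprocess_batch(list(y[1, , , ]), target_size = 16)
  expect_equal(z[1, , , ], y[1, , , ])

  expect_error(preprocess_batch(list(matrix(300.5, 4, 4)), 4), "8-bit")
})

test_that("augmentation is seeded, shape-preserving, and flips are involutions", {
  set.seed(1)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  a1 <- augment_image(img, seed = 42)
  a2 <- augment_image(img, seed = 42)
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(img))

  flipped <- augment_image(img, flip = TRUE, angle = 0)
  expect_identical(augment_image(flipped, flip = TRUE, angle = 0), img)
  expect_false(identical(flipped, img))
})

tiny_fit_setup <- function(n = 8, seed = 1) {
  ds <- generate_dataset(phantom_config(n_benign = n / 2, n_malignant = n / 2,
                                        image_size = 32, seed = seed))
  net <- build_rdn(rdn_config(input_size = 16L, block_widths = c(4L, 8L),
                              dropout_rate = 0.25), seed = seed)
  list(ds = ds, net = net)
}

test_that("one epoch yields one history row and identical seeds identical weights", {
  s <- tiny_fit_setup()
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 7, target_size = 16)
  res <- train_rdn(s$net, s$ds, cfg = cfg)
  expect_equal(nrow(res$history), 1)
  expect_true(is.finite(res$history$loss))

  cfg2 <- train_config(epochs = 2, batch_size = 4, seed = 7, target_size = 16)
  r1 <- train_rdn(s$net, s$ds, cfg = cfg2)
  r2 <- train_rdn(s$net, s$ds, cfg = cfg2)
  expect_identical(r1$net$layers$dense$W, r2$net$layers$dense$W)
  expect_identical(r1$net$layers$conv1$W, r2$net$layers$conv1$W)
  expect_identical(r1$history, r2$history)
})

test_that("training loss decreases on separable phantoms for most seeds", {
  wins <- 0
  for (seed in 1:3) {
    ds <- generate_dataset(phantom_config(n_benign = 12, n_malignant = 12,
                                          image_size = 32, seed = seed))
    net <- build_rdn(rdn_config(input_size = 16L, block_widths = c(4L, 8L),
                                dropout_rate = 0.25), seed = seed)
    res <- train_rdn(net, ds, cfg = train_config(epochs = 5, batch_size = 8,
                                                 seed = seed, target_size = 16))
    if (min(res$history$loss) < res$history$loss[1]) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("a runaway learning rate aborts with a divergence diagnostic", {
  s <- tiny_fit_setup()
  expect_error(
    train_rdn(s$net, s$ds,
              cfg = train_config(epochs = 10, batch_size = 8, seed = 1,
                                 learning_rate = 1e18, optimizer = "sgd",
                                 target_size = 16)),
    "diverged")
})

test_that("evaluation thresholds at 0.5 (ties positive) and matches a counting loop", {
  s <- tiny_fit_setup(n = 12, seed = 5)
  report <- evaluate_model(s$net, s$ds)
  y <- s$ds$items$label
  p <- report$probabilities
  tp <- sum(y == 1 & p >= 0.5); tn <- sum(y == 0 & p < 0.5)
  fp <- sum(y == 0 & p >= 0.5); fn <- sum(y == 1 & p < 0.5)
  expect_equal(unlist(report$counts[c("TP", "TN", "FP", "FN")]),
               c(TP = tp, TN = tn, FP = fp, FN = fn))

  # constant 0.5 predictor: every case is called malignant, so recall is 1
  zero <- s$net
  for (nm in names(zero$layers)) {
    for (par in c("W", "b", "beta")) {
      if (!is.null(zero$layers[[nm]][[par]])) zero$layers[[nm]][[par]][] <- 0
    }
  }
  rep0 <- evaluate_model(zero, s$ds)
  expect_equal(unique(rep0$probabilities), 0.5)
  expect_equal(rep0$metrics$recall, 1)
  expect_equal(rep0$metrics$specificity, 0)

  expect_error(evaluate_model(s$net, list(x = array(0, c(0, 16, 16, 3)),
                                          y = numeric(0))), "empty")
})

test_that("the rdn_fit interface trains, predicts, and exposes model methods", {
  ds <- generate_dataset(phantom_config(n_benign = 15, n_malignant = 15,
                                        image_size = 32, seed = 21))
  fit <- rdn_fit(ds,
                 net_config = rdn_config(input_size = 16L, block_widths = c(4L, 8L),
                                         dropout_rate = 0.25),
                 train = train_config(epochs = 2, batch_size = 8, seed = 2),
                 seed = 2)
  expect_s3_class(fit, "rdn_fit")
  # per-class rounding: round(0.1 * 15) = 2 validation and test images per class
  expect_equal(unname(fit$splits), c(22L, 4L, 4L))
  expect_equal(nrow(fit$history), 2)
  expect_s3_class(fit$evaluation, "eval_report")

  p <- predict(fit, ds)
  expect_length(p, 30)
  expect_true(all(p > 0 & p < 1))
  cls <- predict(fit, ds, type = "class")
  expect_true(all(cls %in% 0:1))

  cf <- coef(fit)
  expect_true("conv1.W" %in% names(cf))
  expect_length(residuals(fit), 4)
  expect_output(print(fit), "Residual depth-wise network fit")
  expect_output(summary(fit), "Evaluation")

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
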