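#' Training configuration
#'
#' Plumbing defaults for the mini-batch training loop; the loss is always
#' binary cross-entropy on the sigmoid output.
#'
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size mini-batch size (>= 1).
#' @param learning_rate optimizer step size (> 0).
#' @param optimizer `"adam"` (adaptive moments) or `"sgd"`.
#' @param seed integer seed covering shuffling, weight initialization, dropout
#'   and augmentation.
#' @param target_size image side length fed to the network; must equal the
#'   network's `input_size`.
#' @param augment apply [augment_image()] to each training image every epoch.
#' @param class_weight `"none"` or `"balanced"` (weight each class inversely
#'   to its frequency in the binary cross-entropy).
#' @param undersample randomly downsample the majority class to the minority
#'   class size each epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 32L, learning_rate = 1e-3,
                         optimizer = c("adam", "sgd"), seed = 1L,
                         target_size = 128L, augment = FALSE,
                         class_weight = c("none", "balanced"),
                         undersample = FALSE) {
  optimizer <- match.arg(optimizer)
  class_weight <- match.arg(class_weight)
  if (!is_count(epochs) || epochs < 1) stopf("`epochs` must be an integer >= 1")
  if (!is_count(batch_size) || batch_size < 1) stopf("`batch_size` must be an integer >= 1")
  if (!is.numeric(learning_rate) || learning_rate <= 0) stopf("`learning_rate` must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 loss = "binary_crossentropy", seed = as.integer(seed),
                 target_size = as.integer(target_size), augment = isTRUE(augment),
                 class_weight = class_weight, undersample = isTRUE(undersample)),
            class = "train_config")
}

# dataset -> list(x = (n, s, s, 3) array in [0,1], y = 0/1 vector)
as_xy <- function(ds, target_size) {
  if (is.list(ds) && !inherits(ds, "labeled_dataset") &&
      all(c("x", "y") %in% names(ds))) {
    return(ds)
  }
  stopifnot(inherits(ds, "labeled_dataset"))
  list(x = preprocess_batch(ds, target_size), y = as.numeric(ds$items$label))
}

adam_state <- function() new.env(parent = emptyenv())

adam_update <- function(layer, grads, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (p in names(grads)) {
    key <- paste0(layer$name, ".", p)
    g <- grads[[p]]
    if (is.null(state[[key]])) state[[key]] <- list(m = g * 0, v = g * 0)
    st <- state[[key]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    state[[key]] <- st
    mhat <- st$m / (1 - b1^t)
    vhat <- st$v / (1 - b2^t)
    layer[[p]] <- layer[[p]] - lr * mhat / (sqrt(vhat) + eps)
  }
  layer
}

# weighted BCE loss and output-gradient for one mini-batch
bce_grad <- function(p, y, w) {
  eps <- 1e-12
  loss <- -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / length(y)
  list(loss = loss, dz = w * (p - y) / length(y))
}

#' Train a residual depth-wise network
#'
#' Minimizes binary cross-entropy by seeded mini-batch gradient descent
#' (Adam by default).  Per-epoch training and validation loss/accuracy are
#' recorded.  All randomness — shuffling, dropout masks, optional
#' augmentation and undersampling — derives from `cfg$seed`, so two runs with
#' the same seed produce identical weights.
#'
#' @param net an [build_rdn()] network whose `input_size` equals
#'   `cfg$target_size`.
#' @param train_ds,val_ds `labeled_dataset`s (validation optional).
#' @param cfg a [train_config()].
#' @return list with `net` (trained network) and `history` (data.frame with
#'   per-epoch `epoch`, `loss`, `accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_rdn <- function(net, train_ds, val_ds = NULL, cfg = train_config()) {
  stopifnot(inherits(net, "rdn_network"), inherits(cfg, "train_config"))
  if (net$cfg$input_size != cfg$target_size) {
    stopf("network input size (%d) must equal cfg$target_size (%d)",
          net$cfg$input_size, cfg$target_size)
  }
  tr <- as_xy(train_ds, cfg$target_size)
  va <- if (!is.null(val_ds)) as_xy(val_ds, cfg$target_size)
  n <- length(tr$y)
  if (!n) stopf("training set is empty")

  w_class <- c(1, 1)
  if (cfg$class_weight == "balanced") {
    n0 <- sum(tr$y == 0); n1 <- sum(tr$y == 1)
    if (n0 > 0 && n1 > 0) w_class <- c(n / (2 * n0), n / (2 * n1))
  }

  state <- adam_state()
  t_step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- seq_len(n)
      if (cfg$undersample) {
        n0 <- which(tr$y == 0); n1 <- which(tr$y == 1)
        k <- min(length(n0), length(n1))
        if (k > 0) idx <- c(sample(n0, k), sample(n1, k))
      }
      idx <- sample(idx)
      ep_loss <- 0; ep_correct <- 0; ep_n <- 0
      for (start in seq(1, length(idx), by = cfg$batch_size)) {
        bi <- idx[start:min(start + cfg$batch_size - 1L, length(idx))]
        xb <- tr$x[bi, , , , drop = FALSE]
        if (cfg$augment) {
          for (j in seq_along(bi)) xb[j, , , ] <- augment_image(xb[j, , , ])
        }
        yb <- tr$y[bi]
        fp <- forward_pass(net, xb, train = TRUE)
        bg <- bce_grad(fp$output, yb, w_class[yb + 1])
        if (!is.finite(bg$loss)) {
          stopf("training diverged at epoch %d (non-finite loss); lower the learning rate",
                epoch)
        }
        # reuse the graph's backward pass with the weighted output gradient
        bp <- backward_pass(net, fp, yb, dz = bg$dz)
        t_step <- t_step + 1L
        for (nm in names(bp$grads)) {
          net$layers[[nm]] <- if (cfg$optimizer == "adam") {
            adam_update(net$layers[[nm]], bp$grads[[nm]], state,
                        cfg$learning_rate, t_step)
          } else {
            l <- net$layers[[nm]]
            for (p in names(bp$grads[[nm]])) {
              l[[p]] <- l[[p]] - cfg$learning_rate * bp$grads[[nm]][[p]]
            }
            l
          }
        }
        # persist batch-norm running statistics
        for (nm in names(fp$caches)) {
          cc <- fp$caches[[nm]]
          if (!is.null(cc$running_mean)) {
            net$layers[[nm]]$running_mean <- cc$running_mean
            net$layers[[nm]]$running_var <- cc$running_var
          }
        }
        ep_loss <- ep_loss + bg$loss * length(bi)
        ep_correct <- ep_correct + sum((fp$output >= 0.5) == (yb == 1))
        ep_n <- ep_n + length(bi)
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(va)) {
        pv <- forward_pass(net, va$x, train = FALSE)$output
        val_loss <- bce_grad(pv, va$y, rep(1, length(va$y)))$loss
        val_acc <- mean((pv >= 0.5) == (va$y == 1))
      }
      history[epoch, ] <- list(epoch, ep_loss / ep_n, ep_correct / ep_n,
                               val_loss, val_acc)
    }
  })
  list(net = net, history = history)
}

#' Evaluate a network on a labeled dataset
#'
#' Runs the network in inference mode, thresholds the malignancy
#' probabilities (values `>= threshold` are called malignant), and computes
#' confusion counts and the five classification metrics.
#'
#' @param net a trained [build_rdn()] network.
#' @param ds a `labeled_dataset` (or `list(x =, y =)`).
#' @param threshold decision threshold in `(0, 1)`, default 0.5.
#' @return An object of class `eval_report`: list with `counts`
#'   ([confusion_counts()]), `metrics` ([compute_metrics()]), `probabilities`,
#'   `labels`, `threshold` and `schema_version`.
#' @export
evaluate_model <- function(net, ds, threshold = 0.5) {
  stopifnot(inherits(net, "rdn_network"))
  xy <- as_xy(ds, net$cfg$input_size)
  if (!length(xy$y)) stopf("cannot evaluate on an empty dataset")
  p <- forward_pass(net, xy$x, train = FALSE)$output
  pred <- as.integer(p >= threshold)
  cc <- confusion_counts(xy$y, pred)
  structure(list(counts = cc, metrics = compute_metrics(cc),
                 probabilities = p, labels = as.integer(xy$y),
                 threshold = threshold, schema_version = "1.0"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation of %d images (threshold %.2f)\n", x$counts$total, x$threshold))
  cat(format_confusion(x$counts), sep = "\n")
  cat("\n")
  print(x$metrics)
  invisible(x)
}

#' Fit a residual depth-wise mammogram classifier
#'
#' The top-level modelling interface: splits a labeled dataset into
#' train/validation/test partitions, builds a residual depth-wise network,
#' trains it with seeded mini-batch gradient descent on binary cross-entropy,
#' and evaluates the result on the held-out test partition.
#'
#' @param data a `labeled_dataset` (from [load_dataset()] or
#'   [generate_dataset()]) or a path accepted by [load_dataset()].
#' @param net_config an [rdn_config()]; its `input_size` drives preprocessing.
#' @param split a [split_config()].
#' @param train a [train_config()] (its `target_size` is aligned to
#'   `net_config$input_size`).
#' @param enhancement optional [fusion_config()] applied to every image before
#'   preprocessing.
#' @param seed master seed for weight initialization.
#' @return An object of class `rdn_fit` with components `network`, `history`,
#'   `evaluation` (test-set [evaluate_model()] report), `splits` (partition
#'   sizes), and the resolved configurations.  Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `plot()` and `residuals()`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(phantom_config(n_benign = 30, n_malignant = 30,
#'                                       image_size = 64, seed = 7))
#' fit <- rdn_fit(ds,
#'                net_config = rdn_config(input_size = 32, block_widths = c(8L, 16L),
#'                                        dropout_rate = 0.25),
#'                train = train_config(epochs = 3, batch_size = 16))
#' print(fit)
#' }
#' @export
rdn_fit <- function(data, net_config = rdn_config(), split = split_config(),
                    train = train_config(target_size = net_config$input_size),
                    enhancement = NULL, seed = 1L) {
  if (is.character(data)) data <- load_dataset(data)
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.null(enhancement)) {
    data$images <- lapply(data$images, apply_fusion, cfg = enhancement)
  }
  train$target_size <- net_config$input_size
  parts <- split_dataset(data, split)
  net <- build_rdn(net_config, seed = seed)
  fitted <- train_rdn(net, parts$train,
                      if (length(parts$val)) parts$val else NULL, train)
  eval_report <- if (length(parts$test)) {
    evaluate_model(fitted$net, parts$test)
  }
  structure(list(network = fitted$net, history = fitted$history,
                 evaluation = eval_report,
                 splits = vapply(parts, length, integer(1)),
                 net_config = net_config, split_config = split,
                 train_config = train, seed = seed,
                 call = match.call()),
            class = "rdn_fit")
}

#' @export
print.rdn_fit <- function(x, ...) {
  cat("Residual depth-wise network fit\n")
  cat(sprintf("  parameters: %d   split (train/val/test): %s\n",
              count_parameters(x$network), paste(x$splits, collapse = "/")))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final epoch %d: loss %.4f, accuracy %.3f", h$epoch, h$loss, h$accuracy))
  if (!is.na(h$val_accuracy)) cat(sprintf(", val accuracy %.3f", h$val_accuracy))
  cat("\n")
  if (!is.null(x$evaluation)) {
    cat(sprintf("  test accuracy: %.3f\n", x$evaluation$metrics$accuracy))
  }
  invisible(x)
}

#' @export
summary.rdn_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$evaluation)) {
    cat("\nTest-set evaluation:\n")
    print(object$evaluation)
  }
  invisible(object)
}

#' @export
coef.rdn_fit <- function(object, ...) {
  out <- list()
  for (l in object$network$layers) {
    for (p in c("W", "b", "gamma", "beta")) {
      if (!is.null(l[[p]])) out[[paste0(l$name, ".", p)]] <- l[[p]]
    }
  }
  out
}

#' @export
predict.rdn_fit <- function(object, newdata, type = c("prob", "class"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "labeled_dataset") || is.list(newdata) &&
           !is.array(newdata)) {
    as_xy(newdata, object$network$cfg$input_size)$x
  } else {
    preprocess_batch(newdata, object$network$cfg$input_size)
  }
  p <- forward_pass(object$network, x, train = FALSE)$output
  if (type == "class") as.integer(p >= threshold) else p
}

#' @export
plot.rdn_fit <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "loss",
                 main = "Training loss", ...)
  if (!all(is.na(h$val_loss))) graphics::lines(h$epoch, h$val_loss, type = "b", lty = 2)
  graphics::plot(h$epoch, h$accuracy, type = "b", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "Accuracy", ...)
  if (!all(is.na(h$val_accuracy))) {
    graphics::lines(h$epoch, h$val_accuracy, type = "b", lty = 2)
  }
  invisible(x)
}

#' @export
residuals.rdn_fit <- function(object, ...) {
  if (is.null(object$evaluation)) return(numeric(0))
  object$evaluation$labels - object$evaluation$probabilities
}
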