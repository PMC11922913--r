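#' Residual depth-wise network configuration
#'
#' The architecture couples a standard entry convolution with residual blocks
#' of depth-wise separable convolutions: a per-channel spatial (depth-wise)
#' convolution followed by 1x1 cross-channel (point-wise) convolutions, with a
#' 1x1-projected additive shortcut around the first block.  This factorization
#' keeps the parameter count far below that of standard convolutions of the
#' same width.
#'
#' @param input_size input image side length in pixels (>= 8), default 128.
#' @param input_channels number of input channels, default 3 (the enhanced
#'   grayscale channel replicated).
#' @param block_widths increasing channel widths of the successive stages,
#'   default `c(32, 64)`.
#' @param padding `"same"` (spatial size preserved, the canonical setting) or
#'   `"valid"` (a k x k kernel shrinks each side by k - 1).
#' @param use_batch_norm normalize each depth-wise stage's output over the
#'   batch before its activation, default `TRUE`.
#' @param dropout_rate fraction of pre-flatten activations zeroed during
#'   training, in `[0, 1)`, default 0.5; 0 disables the layer.
#' @param output_units units of the classification head, default 1 (benign vs
#'   malignant through a sigmoid).
#' @return an object of class `rdn_config`.
#' @export
rdn_config <- function(input_size = 128L, input_channels = 3L,
                       block_widths = c(32L, 64L),
                       padding = c("same", "valid"),
                       use_batch_norm = TRUE, dropout_rate = 0.5,
                       output_units = 1L) {
  padding <- match.arg(padding)
  if (!is_count(input_size) || input_size < 8L) stopf("`input_size` must be an integer >= 8")
  block_widths <- as.integer(block_widths)
  if (!length(block_widths) || anyNA(block_widths) || any(block_widths < 1L)) {
    stopf("`block_widths` must be positive integers")
  }
  if (is.unsorted(block_widths, strictly = TRUE)) {
    stopf("`block_widths` must be increasing, got (%s)",
          paste(block_widths, collapse = ", "))
  }
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stopf("`dropout_rate` must be in [0, 1)")
  }
  structure(list(input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 block_widths = block_widths,
                 padding = padding,
                 use_batch_norm = isTRUE(use_batch_norm),
                 dropout_rate = dropout_rate,
                 output_units = as.integer(output_units)),
            class = "rdn_config")
}

layer_spec <- function(name, kind, from, ...) {
  c(list(name = name, kind = kind, from = from), list(...))
}

init_conv <- function(kh, kw, cin, cout, he = TRUE) {
  fan_in <- kh * kw * cin
  sd <- if (he) sqrt(2 / fan_in) else sqrt(1 / fan_in)
  list(W = array(stats::rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout)),
       b = numeric(cout))
}

#' Build a residual depth-wise network
#'
#' Assembles the layer graph for a [rdn_config()] and initializes weights from
#' a seeded He-style generator.  For the default configuration the chain is:
#' entry 3x3 convolution (ReLU) -> depth-wise 3x3 (+ batch norm, ReLU) ->
#' point-wise 1x1 -> additive shortcut (1x1 projection of the entry
#' convolution's output) -> point-wise 1x1 to the next width (ReLU) ->
#' depth-wise 3x3 (+ batch norm, ReLU) -> point-wise 1x1 (ReLU) -> dropout ->
#' flatten -> dense sigmoid head.  Shape consistency, including equality of
#' the two addition operands, is verified at construction.
#'
#' @param cfg a [rdn_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `rdn_network`.
#' @examples
#' net <- build_rdn(rdn_config(input_size = 16, block_widths = c(4L, 8L)), seed = 1)
#' shape_table(net)
#' @export
build_rdn <- function(cfg = rdn_config(), seed = 1L) {
  if (!inherits(cfg, "rdn_config")) stopf("`cfg` must be an rdn_config")
  w <- cfg$block_widths
  layers <- list(layer_spec("input", "input", character(0)))
  add_layer <- function(l) layers[[length(layers) + 1L]] <<- l
  dw_stage <- function(idx, from) {
    dw_name <- paste0("dw", idx)
    add_layer(layer_spec(dw_name, "depthwise", from, kernel = c(3L, 3L),
                         padding = cfg$padding))
    prev <- dw_name
    if (cfg$use_batch_norm) {
      bn <- paste0("bn", idx)
      add_layer(layer_spec(bn, "batch_norm", prev))
      prev <- bn
    }
    act <- paste0("dw", idx, "_relu")
    add_layer(layer_spec(act, "activation", prev, activation = "relu"))
    act
  }

  add_layer(layer_spec("conv1", "conv", "input", filters = w[1],
                       kernel = c(3L, 3L), padding = cfg$padding,
                       activation = "relu"))
  prev <- dw_stage(1L, "conv1")
  add_layer(layer_spec("pw1", "conv", prev, filters = w[1],
                       kernel = c(1L, 1L), padding = cfg$padding,
                       activation = "none"))
  add_layer(layer_spec("shortcut", "conv", "conv1", filters = w[1],
                       kernel = c(1L, 1L), padding = cfg$padding,
                       activation = "none"))
  add_layer(layer_spec("add1", "add", c("pw1", "shortcut")))
  prev <- "add1"
  for (i in seq_along(w)[-1]) {
    expand <- paste0("pw", i, "_expand")
    add_layer(layer_spec(expand, "conv", prev, filters = w[i],
                         kernel = c(1L, 1L), padding = cfg$padding,
                         activation = "relu"))
    prev <- dw_stage(i, expand)
    proj <- paste0("pw", i, "_project")
    add_layer(layer_spec(proj, "conv", prev, filters = w[i],
                         kernel = c(1L, 1L), padding = cfg$padding,
                         activation = "relu"))
    prev <- proj
  }
  if (cfg$dropout_rate > 0) {
    add_layer(layer_spec("dropout", "dropout", prev, rate = cfg$dropout_rate))
    prev <- "dropout"
  }
  add_layer(layer_spec("flatten", "flatten", prev))
  add_layer(layer_spec("dense", "dense", "flatten", units = cfg$output_units,
                       activation = "sigmoid"))

  net <- structure(list(cfg = cfg, layers = layers), class = "rdn_network")
  shapes <- propagate_shapes(net, cfg$input_size)   # errors on any mismatch

  # seeded parameter initialization
  net$layers <- with_seed(seed, {
    lapply(net$layers, function(l) {
      in_shape <- if (length(l$from)) shapes[[l$from[1]]] else NULL
      switch(l$kind,
             conv = {
               p <- init_conv(l$kernel[1], l$kernel[2], in_shape[3], l$filters)
               c(l, p)
             },
             depthwise = {
               C <- in_shape[3]
               c(l, list(W = array(stats::rnorm(prod(l$kernel) * C,
                                                sd = sqrt(2 / prod(l$kernel))),
                                   c(l$kernel, C)),
                         b = numeric(C)))
             },
             batch_norm = c(l, list(gamma = rep(1, in_shape[3]),
                                    beta = numeric(in_shape[3]),
                                    running_mean = numeric(in_shape[3]),
                                    running_var = rep(1, in_shape[3]))),
             dense = {
               D <- in_shape[1]
               c(l, list(W = matrix(stats::rnorm(D * l$units, sd = sqrt(1 / D)),
                                    D, l$units),
                         b = numeric(l$units)))
             },
             l)
    })
  })
  names(net$layers) <- vapply(net$layers, `[[`, character(1), "name")
  net
}

conv_out_hw <- function(hw, kernel, padding) {
  if (padding == "same") hw else hw - kernel + 1L
}

# analytic shape propagation; errors if the add operands disagree
propagate_shapes <- function(net, input_size = NULL) {
  cfg <- net$cfg
  size <- as.integer(input_size %||% cfg$input_size)
  shapes <- list()
  for (l in net$layers) {
    shapes[[l$name]] <- switch(l$kind,
      input = c(size, size, cfg$input_channels),
      conv = {
        s <- shapes[[l$from]]
        c(conv_out_hw(s[1:2], l$kernel, l$padding), l$filters)
      },
      depthwise = {
        s <- shapes[[l$from]]
        c(conv_out_hw(s[1:2], l$kernel, l$padding), s[3])
      },
      max_pool = {
        s <- shapes[[l$from]]
        c(s[1:2] %/% (l$pool %||% 2L), s[3])
      },
      add = {
        a <- shapes[[l$from[1]]]; b <- shapes[[l$from[2]]]
        if (!identical(a, b)) {
          stopf("add layer '%s': operand shapes (%s) and (%s) differ",
                l$name, paste(a, collapse = ", "), paste(b, collapse = ", "))
        }
        a
      },
      flatten = prod(shapes[[l$from]]),
      dense = l$units,
      shapes[[l$from]])   # batch_norm / activation / dropout: unchanged
  }
  shapes
}

layer_label <- function(l, shape) {
  switch(l$kind,
    input = "Input layer",
    conv = {
      if (l$name == "shortcut") {
        sprintf("Shortcut (Conv2D, %d x %d)", l$kernel[1], l$kernel[2])
      } else {
        sprintf("Conv2D (%d filters, %d x %d)", l$filters, l$kernel[1], l$kernel[2])
      }
    },
    depthwise = sprintf("DepthwiseConv2D (%d x %d)", l$kernel[1], l$kernel[2]),
    batch_norm = "BatchNormalization",
    activation = sprintf("Activation (%s)", l$activation),
    add = "Add layer (skip connection)",
    max_pool = sprintf("MaxPooling2D (%d x %d)", l$pool %||% 2L, l$pool %||% 2L),
    dropout = sprintf("Dropout (%.2g)", l$rate),
    flatten = "Flatten",
    dense = sprintf("Dense (%d unit%s, %s)", l$units,
                    if (l$units > 1) "s" else "",
                    if (identical(l$activation, "sigmoid")) "Sigmoid" else l$activation),
    l$kind)
}

#' Per-layer output-shape table
#'
#' Propagates output shapes analytically through the layer graph: `same`
#' padding preserves spatial size, `valid` padding shrinks each side by
#' `kernel - 1`, pooling divides by the pool size, flatten multiplies out the
#' dimensions.  By default, shape-preserving auxiliary layers (batch
#' normalization, activations, dropout) are folded into their parent row so
#' the table matches the conventional architecture summary; set
#' `include_aux = TRUE` to list every layer.
#'
#' @param net an [build_rdn()] network.
#' @param input_size optional input side length overriding the network's.
#' @param include_aux list auxiliary layers as their own rows.
#' @return a `data.frame` with columns `layer` (label) and `output_shape`
#'   (printed shape) plus a `shapes` attribute holding the integer vectors.
#' @export
shape_table <- function(net, input_size = NULL, include_aux = FALSE) {
  stopifnot(inherits(net, "rdn_network"))
  shapes <- propagate_shapes(net, input_size)
  keep <- vapply(net$layers, function(l) {
    include_aux || !(l$kind %in% c("batch_norm", "activation", "dropout"))
  }, logical(1))
  layers <- net$layers[keep]
  fmt <- function(s) {
    if (length(s) == 1L) sprintf("(%d)", s) else sprintf("(%s)", paste(s, collapse = ", "))
  }
  df <- data.frame(
    layer = vapply(layers, function(l) layer_label(l, shapes[[l$name]]), character(1)),
    output_shape = vapply(layers, function(l) fmt(shapes[[l$name]]), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(df, "shapes") <- shapes[vapply(layers, `[[`, character(1), "name")]
  df
}

#' Total trainable parameter count
#'
#' Standard formulas per layer kind: `kh*kw*Cin*Cout + Cout` for convolutions,
#' `kh*kw*C + C` for depth-wise convolutions, `2C` for batch normalization,
#' `D*U + U` for dense layers.
#'
#' @param net an [build_rdn()] network.
#' @return integer parameter count.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "rdn_network"))
  sum(vapply(net$layers, function(l) {
    n <- 0
    for (p in c("W", "b", "gamma", "beta")) if (!is.null(l[[p]])) n <- n + length(l[[p]])
    n
  }, numeric(1)))
}

#' @export
print.rdn_network <- function(x, ...) {
  tb <- shape_table(x)
  cat(sprintf("Residual depth-wise network (%d parameters)\n", count_parameters(x)))
  cat(sprintf("  %-34s %s\n", "Layer", "Output shape"))
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-34s %s\n", tb$layer[i], tb$output_shape[i]))
  }
  invisible(x)
}

# Full forward pass.  x: array (N, H, W, C) or (H, W, C).  Returns activations
# and caches keyed by layer name; "output" holds the probabilities.
forward_pass <- function(net, x, train = FALSE) {
  cfg <- net$cfg
  if (length(dim(x)) == 3L) x <- array(x, c(1L, dim(x)))
  d <- dim(x)
  if (length(d) != 4L || d[2] != cfg$input_size || d[3] != cfg$input_size ||
      d[4] != cfg$input_channels) {
    stopf("input batch must be shaped (n, %d, %d, %d), got (%s)",
          cfg$input_size, cfg$input_size, cfg$input_channels,
          paste(d, collapse = ", "))
  }
  a <- aperm(x, c(2, 3, 4, 1))                  # (H, W, C, N)
  acts <- list(); caches <- list()
  for (l in net$layers) {
    out <- switch(l$kind,
      input = a,
      conv = {
        pad <- if (l$padding == "same") (l$kernel[1] - 1L) %/% 2L else 0L
        cc <- conv2d_forward(acts[[l$from]], l$W, l$b, pad)
        caches[[l$name]] <- cc
        z <- cc$out
        if (identical(l$activation, "relu")) {
          caches[[l$name]]$pre <- z
          z <- relu_fwd(z)
        }
        z
      },
      depthwise = {
        pad <- if (l$padding == "same") (l$kernel[1] - 1L) %/% 2L else 0L
        caches[[l$name]] <- list(pad = pad)
        depthwise_forward(acts[[l$from]], l$W, l$b, pad)
      },
      batch_norm = {
        bn <- batchnorm_forward(acts[[l$from]], l$gamma, l$beta,
                                l$running_mean, l$running_var, train)
        caches[[l$name]] <- bn
        bn$out
      },
      activation = {
        z <- acts[[l$from]]
        caches[[l$name]] <- list(pre = z)
        relu_fwd(z)
      },
      add = acts[[l$from[1]]] + acts[[l$from[2]]],
      max_pool = maxpool_forward(acts[[l$from]], l$pool %||% 2L),
      dropout = {
        z <- acts[[l$from]]
        if (train && l$rate > 0) {
          mask <- array(dropout_mask(length(z), l$rate), dim(z))
          caches[[l$name]] <- list(mask = mask)
          z * mask
        } else z
      },
      flatten = {
        z <- acts[[l$from]]
        dz <- dim(z)
        matrix(z, dz[1] * dz[2] * dz[3], dz[4])  # (D, N)
      },
      dense = {
        z <- crossprod(l$W, acts[[l$from]])      # (U, N)
        z <- z + l$b
        caches[[l$name]] <- list(pre = z)
        if (identical(l$activation, "sigmoid")) sigmoid_fwd(z) else z
      },
      stopf("forward not implemented for layer kind '%s'", l$kind))
    acts[[l$name]] <- out
  }
  last <- net$layers[[length(net$layers)]]$name
  list(acts = acts, caches = caches, output = as.numeric(acts[[last]]))
}

#' Training-time dropout mask
#'
#' The inverted-dropout mask the network's dropout layer multiplies its input
#' by during training: each unit is independently zeroed with probability
#' `rate` and surviving units are scaled by `1 / (1 - rate)` so the expected
#' activation is unchanged.
#'
#' @param n number of units.
#' @param rate dropout fraction in `[0, 1)`.
#' @return numeric vector of length `n` with values 0 or `1 / (1 - rate)`.
#' @export
dropout_mask <- function(n, rate = 0.5) {
  if (rate < 0 || rate >= 1) stopf("`rate` must be in [0, 1)")
  (stats::runif(n) >= rate) / (1 - rate)
}

#' Run the network on a batch of images
#'
#' @param net an [build_rdn()] network.
#' @param batch array shaped `(n, input_size, input_size, channels)` — or a
#'   single `(input_size, input_size, channels)` image — with values in
#'   `[0, 1]`.
#' @param train_mode activate dropout and batch statistics (training-time
#'   behavior); default `FALSE` uses running statistics and no dropout.
#' @param seed optional seed controlling dropout masks in train mode.
#' @return numeric vector of per-image probabilities in `(0, 1)` that the
#'   image is malignant.
#' @export
rdn_forward <- function(net, batch, train_mode = FALSE, seed = NULL) {
  stopifnot(inherits(net, "rdn_network"))
  res <- with_seed(seed, forward_pass(net, batch, train = train_mode))
  res$output
}

# Backward pass for binary cross-entropy on sigmoid output.  `dz` may
# override the output-logit gradient (used for class-weighted training).
# Returns gradients keyed by layer name and the mean BCE loss.
backward_pass <- function(net, fp, y, dz = NULL) {
  acts <- fp$acts; caches <- fp$caches
  n <- length(y)
  p <- fp$output
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  grads <- list()
  dacts <- list()
  bump <- function(name, g) {
    dacts[[name]] <<- if (is.null(dacts[[name]])) g else dacts[[name]] + g
  }
  last <- net$layers[[length(net$layers)]]
  # d loss / d pre-sigmoid logits
  dz <- matrix(dz %||% ((p - y) / n), nrow = last$units)
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (l$kind == "input") next
    dy <- if (identical(l$name, last$name)) dz else dacts[[l$name]]
    if (is.null(dy)) next
    switch(l$kind,
      dense = {
        x <- acts[[l$from]]
        grads[[l$name]] <- list(W = x %*% t(dy), b = rowSums(dy))
        bump(l$from, l$W %*% dy)
      },
      flatten = {
        up <- dim(acts[[l$from]])
        bump(l$from, array(dy, up))
      },
      dropout = {
        mask <- caches[[l$name]]$mask
        bump(l$from, if (is.null(mask)) dy else dy * mask)
      },
      add = {
        bump(l$from[1], dy)
        bump(l$from[2], dy)
      },
      activation = {
        bump(l$from, dy * (caches[[l$name]]$pre > 0))
      },
      batch_norm = {
        bn <- batchnorm_backward(dy, l$gamma, caches[[l$name]])
        grads[[l$name]] <- list(gamma = bn$dgamma, beta = bn$dbeta)
        bump(l$from, bn$dx)
      },
      depthwise = {
        dd <- depthwise_backward(dy, acts[[l$from]], l$W, caches[[l$name]]$pad)
        grads[[l$name]] <- list(W = dd$dW, b = dd$db)
        bump(l$from, dd$dx)
      },
      conv = {
        if (identical(l$activation, "relu")) dy <- dy * (caches[[l$name]]$pre > 0)
        cb <- conv2d_backward(dy, acts[[l$from]], l$W, caches[[l$name]])
        grads[[l$name]] <- list(W = cb$dW, b = cb$db)
        bump(l$from, cb$dx)
      },
      max_pool = {
        bump(l$from, maxpool_backward(dy, acts[[l$from]], l$pool %||% 2L))
      },
      stopf("backward not implemented for layer kind '%s'", l$kind))
  }
  list(grads = grads, loss = loss)
}
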