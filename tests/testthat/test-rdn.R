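# Reference shape arithmetic used to cross-check the propagator.
ref_conv_side <- function(s, k, padding) if (padding == "same") s else s - k + 1L

test_that("the default network's shape table matches the canonical layer table", {
  net <- build_rdn(rdn_config(), seed = 1)
  tb <- shape_table(net)
  expect_equal(tb$output_shape,
               c("(128, 128, 3)", "(128, 128, 32)", "(128, 128, 32)",
                 "(128, 128, 32)", "(128, 128, 32)", "(128, 128, 32)",
                 "(128, 128, 64)", "(128, 128, 64)", "(128, 128, 64)",
                 "(1048576)", "(1)"))
  expect_equal(tb$layer,
               c("Input layer", "Conv2D (32 filters, 3 x 3)",
                 "DepthwiseConv2D (3 x 3)", "Conv2D (32 filters, 1 x 1)",
                 "Shortcut (Conv2D, 1 x 1)", "Add layer (skip connection)",
                 "Conv2D (64 filters, 1 x 1)", "DepthwiseConv2D (3 x 3)",
                 "Conv2D (64 filters, 1 x 1)", "Flatten",
                 "Dense (1 unit, Sigmoid)"))
})

test_that("valid-padding convolution and max pooling shrink shapes as expected", {
  # a bare conv + pool chain through the same propagator
  mini <- structure(list(
    cfg = rdn_config(input_size = 128L),
    layers = list(rdnet:::layer_spec("input", "input", character(0)),
                  rdnet:::layer_spec("conv1", "conv", "input", filters = 32L,
                                     kernel = c(3L, 3L), padding = "valid",
                                     activation = "relu"),
                  rdnet:::layer_spec("pool", "max_pool", "conv1", pool = 2L))),
    class = "rdn_network")
  shapes <- attr(shape_table(mini), "shapes")
  expect_equal(shapes$conv1, c(126L, 126L, 32L))
  expect_equal(shapes$pool, c(63L, 63L, 32L))
})

test_that("shape propagation agrees with independent arithmetic over a config grid", {
  for (size in c(32L, 64L, 128L)) {
    # full residual network: same padding end to end
    net <- build_rdn(rdn_config(input_size = size, block_widths = c(8L, 16L)), seed = 1)
    shapes <- attr(shape_table(net, include_aux = TRUE), "shapes")
    expect_equal(shapes$conv1, c(size, size, 8L))
    expect_equal(shapes$dw1, c(size, size, 8L))
    expect_equal(shapes$add1, c(size, size, 8L))
    expect_equal(shapes$pw2_expand, c(size, size, 16L))
    expect_equal(shapes$flatten, size * size * 16L)
    expect_equal(shapes$dense, 1L)

    # linear conv/depthwise chain under both padding modes
    for (pad in c("same", "valid")) {
      chain <- structure(list(
        cfg = rdn_config(input_size = size),
        layers = list(rdnet:::layer_spec("input", "input", character(0)),
                      rdnet:::layer_spec("c1", "conv", "input", filters = 8L,
                                         kernel = c(3L, 3L), padding = pad,
                                         activation = "relu"),
                      rdnet:::layer_spec("d1", "depthwise", "c1",
                                         kernel = c(3L, 3L), padding = pad),
                      rdnet:::layer_spec("c2", "conv", "d1", filters = 16L,
                                         kernel = c(1L, 1L), padding = pad,
                                         activation = "none"))),
        class = "rdn_network")
      shapes <- rdnet:::propagate_shapes(chain)
      s <- ref_conv_side(size, 3L, pad)
      expect_equal(shapes$c1, c(s, s, 8L))
      s <- ref_conv_side(s, 3L, pad)
      expect_equal(shapes$d1, c(s, s, 8L))
      expect_equal(shapes$c2, c(s, s, 16L))   # 1x1 keeps spatial size
    }
  }
})

test_that("valid padding breaks the residual add and construction reports both shapes", {
  expect_error(build_rdn(rdn_config(padding = "valid")), "shapes .* differ")
})

test_that("scaled-down configurations build with matching add operands", {
  net <- build_rdn(rdn_config(input_size = 16L, block_widths = 8L), seed = 2)
  shapes <- rdnet:::propagate_shapes(net)
  expect_equal(shapes$pw1[3], 8L)
  expect_equal(shapes$shortcut[3], 8L)
  expect_equal(shapes$add1, c(16L, 16L, 8L))
  expect_error(rdn_config(block_widths = c(32L, 16L)), "increasing")
})

test_that("forward outputs are probabilities, deterministic, and shape-checked", {
  cfg <- rdn_config(input_size = 16L, block_widths = c(4L, 8L))
  net <- build_rdn(cfg, seed = 5)
  set.seed(1)
  x <- array(runif(3 * 16 * 16 * 3), c(3, 16, 16, 3))
  p1 <- rdn_forward(net, x)
  p2 <- rdn_forward(net, x)
  expect_identical(p1, p2)
  expect_length(p1, 3)
  expect_true(all(p1 > 0 & p1 < 1))

  # zeroed weights force sigmoid(0) = 0.5
  zero <- net
  for (nm in names(zero$layers)) {
    for (p in c("W", "b", "beta")) {
      if (!is.null(zero$layers[[nm]][[p]])) {
        zero$layers[[nm]][[p]][] <- 0
      }
    }
  }
  expect_equal(rdn_forward(zero, x), rep(0.5, 3))

  expect_error(rdn_forward(net, array(0, c(2, 8, 8, 3))), "\\(n, 16, 16, 3\\)")
})

test_that("an identity shortcut with a zeroed main path passes the block input through", {
  cfg <- rdn_config(input_size = 12L, block_widths = c(6L, 8L))
  net <- build_rdn(cfg, seed = 3)
  for (nm in c("dw1", "pw1")) {
    net$layers[[nm]]$W[] <- 0
    net$layers[[nm]]$b[] <- 0
  }
  net$layers$bn1$beta[] <- 0
  net$layers$shortcut$W[] <- 0
  for (c in 1:6) net$layers$shortcut$W[1, 1, c, c] <- 1
  net$layers$shortcut$b[] <- 0
  set.seed(2)
  x <- array(runif(2 * 12 * 12 * 3), c(2, 12, 12, 3))
  fp <- rdnet:::forward_pass(net, x)
  expect_equal(fp$acts$add1, fp$acts$conv1, tolerance = 1e-12)
})

test_that("a depthwise + pointwise pair reproduces a rank-1 standard convolution", {
  set.seed(11)
  Cin <- 3L; Cout <- 2L
  g <- matrix(rnorm(9), 3, 3)           # shared spatial kernel
  v <- rnorm(Cin); u <- rnorm(Cout)     # channel factors
  Wfull <- array(0, c(3, 3, Cin, Cout))
  for (c in seq_len(Cin)) for (o in seq_len(Cout)) Wfull[, , c, o] <- g * v[c] * u[o]

  x <- array(rnorm(4 * 4 * Cin), c(4, 4, Cin))
  want <- oracle_conv2d(x, Wfull, numeric(Cout), pad = 1)

  xb <- array(x, c(4, 4, Cin, 1))
  Wdw <- array(0, c(3, 3, Cin))
  for (c in seq_len(Cin)) Wdw[, , c] <- g * v[c]
  mid <- rdnet:::depthwise_forward(xb, Wdw, numeric(Cin), pad = 1L)
  Wpw <- array(0, c(1, 1, Cin, Cout))
  for (c in seq_len(Cin)) for (o in seq_len(Cout)) Wpw[1, 1, c, o] <- u[o]
  got <- rdnet:::conv2d_forward(mid, Wpw, numeric(Cout), pad = 0L)$out
  expect_equal(got[, , , 1], want, tolerance = 1e-10)

  # and the package's standard convolution matches the brute-force oracle too
  direct <- rdnet:::conv2d_forward(xb, Wfull, numeric(Cout), pad = 1L)$out
  expect_equal(direct[, , , 1], want, tolerance = 1e-10)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- rdn_config(input_size = 8L, block_widths = c(3L, 5L), dropout_rate = 0)
  net <- build_rdn(cfg, seed = 3)
  set.seed(9)
  x <- array(runif(2 * 8 * 8 * 3), c(2, 8, 8, 3))
  y <- c(1, 0)
  fp <- rdnet:::forward_pass(net, x, train = TRUE)
  bp <- rdnet:::backward_pass(net, fp, y)
  loss_at <- function(net) {
    p <- rdnet:::forward_pass(net, x, train = TRUE)$output
    -mean(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12))
  }
  params <- list(c("conv1", "W"), c("conv1", "b"), c("dw1", "W"),
                 c("bn1", "gamma"), c("bn1", "beta"), c("pw1", "W"),
                 c("shortcut", "W"), c("pw2_expand", "W"), c("dw2", "W"),
                 c("dense", "b"))
  set.seed(4)
  for (pr in params) {
    layer <- pr[1]; pname <- pr[2]
    idx <- sample(length(net$layers[[layer]][[pname]]), 1)
    h <- 1e-5
    np <- nm <- net
    np$layers[[layer]][[pname]][idx] <- np$layers[[layer]][[pname]][idx] + h
    nm$layers[[layer]][[pname]][idx] <- nm$layers[[layer]][[pname]][idx] - h
    num <- (loss_at(np) - loss_at(nm)) / (2 * h)
    ana <- bp$grads[[layer]][[pname]][idx]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("parameter counting follows the standard formulas and rewards separability", {
  net <- build_rdn(rdn_config(input_size = 16L, block_widths = c(4L, 8L)), seed = 1)
  # dense layer: D weights + 1 bias
  expect_equal(length(net$layers$dense$W) + length(net$layers$dense$b),
               16 * 16 * 8 + 1)
  # depthwise 3x3 over C channels: 9C weights + C biases
  expect_equal(length(net$layers$dw2$W) + length(net$layers$dw2$b), 8 * 9 + 8)

  default_net <- build_rdn(rdn_config(), seed = 1)
  expect_equal(count_parameters(default_net),
               sum(vapply(default_net$layers, function(l) {
                 sum(lengths(l[c("W", "b", "gamma", "beta")][
                   !vapply(l[c("W", "b", "gamma", "beta")], is.null, logical(1))]))
               }, numeric(1))))
  # replacing each depthwise stage by a full 3x3 convolution costs more
  dw_params <- function(C) 9 * C + C
  full_params <- function(C) 9 * C * C + C
  expect_lt(count_parameters(default_net),
            count_parameters(default_net) - dw_params(32) - dw_params(64) +
              full_params(32) + full_params(64))
})

test_that("dropout masks zero the configured fraction and rescale survivors", {
  set.seed(123)
  m <- dropout_mask(1e5, 0.3)
  expect_true(all(m %in% c(0, 1 / 0.7)))
  expect_equal(mean(m == 0), 0.3, tolerance = 0.01)
  expect_equal(mean(m), 1, tolerance = 0.01)
  expect_error(dropout_mask(10, 1), "rate")
})
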