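# Backbone architectures: channel schedules, layer counts, block
# contracts, forward shape contracts at tiny widths, compound scaling.

test_that("simple CNN follows the f, 2f, 3f schedule and emits C logits", {
  cfg <- backbone_config("simple_cnn", input_resolution = c(36, 36),
                         base_filters = 4L, n_classes = 2L)
  m <- build_simple_cnn(cfg, seed = 1)
  expect_identical(m$conv_channels, c(4L, 8L, 12L))
  x <- array(stats::runif(36 * 36 * 3), c(36, 36, 3, 1))
  s <- m$fw(x, training = FALSE)
  expect_identical(dim(s), c(2L, 1L))
  # doubling f doubles every conv channel count
  cfg2 <- backbone_config("simple_cnn", input_resolution = c(36, 36),
                          base_filters = 8L, n_classes = 2L)
  m2 <- build_simple_cnn(cfg2, seed = 1)
  expect_identical(m2$conv_channels, 2L * m$conv_channels)
  # the headline configuration: f = 128 means a 128-channel first conv
  cfg3 <- backbone_config("simple_cnn", input_resolution = c(150, 200),
                          base_filters = 128L, n_classes = 5L)
  expect_error(build_simple_cnn(cfg3, seed = 1), "divisible")
  cfg4 <- backbone_config("simple_cnn", input_resolution = c(152, 200),
                          base_filters = 128L, n_classes = 5L)
  m4 <- build_simple_cnn(cfg4, seed = 1)
  expect_identical(m4$conv_channels[1], 128L)
})

test_that("depthwise-separable blocks clip at 6 and have 9*in + in*out kernel weights", {
  blk <- leafnet:::ln_seq(list(leafnet:::ln_act("relu6")))
  x <- array(7 + stats::runif(8 * 8 * 2), c(8, 8, 2, 1))
  expect_true(all(blk$fw(x) == 6))
  for (io in list(c(4L, 8L), c(8L, 16L), c(3L, 5L))) {
    b <- depthwise_separable_block(io[1], io[2], stride = 1L)
    expect_identical(block_conv_param_count(b),
                     9 * io[1] + io[1] * io[2])
  }
  # stride 2 halves even spatial dims
  b2 <- depthwise_separable_block(4L, 8L, stride = 2L)
  y <- b2$fw(array(stats::runif(16 * 16 * 4), c(16, 16, 4, 1)))
  expect_identical(dim(y)[1:2], c(8L, 8L))
})

test_that("MobileNet V1 has 28 counted layers and 1024 pre-pool channels", {
  cfg <- backbone_config("mobilenet_v1", input_resolution = 224,
                         n_classes = 10L)
  m <- build_mobilenet_v1(cfg, seed = 1)
  expect_identical(layer_count(m), 28L)
  expect_identical(m$prepool_channels, 1024L)
  # layer count is invariant to the width multiplier
  cfg_small <- backbone_config("mobilenet_v1", input_resolution = 64,
                               width_multiplier = 0.25, n_classes = 5L)
  ms <- build_mobilenet_v1(cfg_small, seed = 1)
  expect_identical(layer_count(ms), 28L)
  s <- ms$fw(array(stats::runif(64 * 64 * 3), c(64, 64, 3, 1)))
  expect_identical(dim(s), c(5L, 1L))
})

test_that("MobileNet V2 matches its bottleneck table", {
  cfg <- backbone_config("mobilenet_v2", input_resolution = 224,
                         n_classes = 4L)
  m <- build_mobilenet_v2(cfg, seed = 1)
  expect_identical(m$prepool_channels, 1280L)
  expect_identical(m$n_bottlenecks, 17L)  # sum of the repeat column
  # skip-connection contract: stride 1 and matching channels
  set.seed(2)
  blk <- leafnet:::ln_inverted_residual(6L, 6L, t = 6L, stride = 1L)
  expect_true(blk$use_skip)
  x <- array(stats::rnorm(8 * 8 * 6), c(8, 8, 6, 1))
  y <- blk$fw(x, training = FALSE)
  branch <- blk$body$fw(x, training = FALSE)
  expect_equal(y, branch + x, tolerance = 1e-12)
  blk2 <- leafnet:::ln_inverted_residual(6L, 8L, t = 6L, stride = 1L)
  expect_false(blk2$use_skip)
  blk3 <- leafnet:::ln_inverted_residual(6L, 6L, t = 6L, stride = 2L)
  expect_false(blk3$use_skip)
})

test_that("EfficientNet B0 has 16 MBConv blocks, 320 then 1280 channels", {
  cfg <- backbone_config("efficientnet_b0", input_resolution = 224,
                         n_classes = 7L)
  m <- build_efficientnet_b0(cfg, seed = 1)
  expect_identical(m$n_mbconv, 16L)        # 1+2+2+3+3+4+1
  expect_identical(m$prepool_channels, 1280L)
  expect_identical(utils::tail(cfg$stages$c, 1), 320L)
  # tiny-width forward shape contract
  cfg_small <- backbone_config("efficientnet_b0", input_resolution = 32,
                               width_multiplier = 0.125, n_classes = 3L)
  ms <- build_efficientnet_b0(cfg_small, seed = 1)
  s <- ms$fw(array(stats::runif(32 * 32 * 3), c(32, 32, 3, 1)))
  expect_identical(dim(s), c(3L, 1L))
})

test_that("MBConv blocks expand channels and the SE gate saturates to identity", {
  set.seed(3)
  blk <- mbconv_block(4L, 4L, expansion = 3L, kernel_size = 3L,
                      stride = 1L, se_ratio = 0.5)
  # channel count after the expansion conv is expansion * in_channels
  expand_conv <- blk$body$children[[1]]
  expect_identical(expand_conv$out_c, 12L)
  # saturate the SE gate: huge positive bias in its second dense layer
  se <- Filter(function(l) l$kind == "se", blk$body$children)[[1]]
  se$fc2$params$b[] <- 1e6
  x <- array(stats::rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  gated <- blk$fw(x, training = FALSE)
  se$fc2$params$b[] <- 1e6  # unchanged; compare against manual ungated path
  # with a saturated sigmoid the gate multiplies by 1: recompute by
  # temporarily replacing the gate with identity
  y_se <- se$fw(se$cache$x, training = FALSE)
  expect_equal(y_se, se$cache$x, tolerance = 1e-9)
  expect_identical(dim(gated), dim(x))
})

test_that("compound scaling: identity at phi = 0, ceil depths, rounded widths", {
  base <- backbone_config("efficientnet_b0", n_classes = 5L)
  c0 <- scaling_coefficients(0, alpha = 1.2, beta = 1.1, gamma = 1.15)
  same <- suppressWarnings(apply_compound_scaling(c0, base))
  expect_identical(same$stages, base$stages)
  expect_identical(same$input_resolution, base$input_resolution)
  # alpha = 2, phi = 1: depths double, channels/resolution unchanged;
  # alpha * beta^2 * gamma^2 = 2 exactly, so the constraint warning stays quiet
  c1 <- scaling_coefficients(1, alpha = 2, beta = 1, gamma = 1)
  expect_no_warning(sc <- apply_compound_scaling(c1, base))
  expect_identical(sc$stages$n, as.integer(2 * base$stages$n))
  expect_warning(apply_compound_scaling(
    scaling_coefficients(1, alpha = 3, beta = 1, gamma = 1), base),
    "deviates")
  expect_identical(sc$stages$c, base$stages$c)
  expect_identical(sc$input_resolution, base$input_resolution)
  # d = 1.2 on a 3-repeat stage gives ceil(3.6) = 4
  c2 <- scaling_coefficients(1, alpha = 1.2, beta = 1, gamma = 1)
  sc2 <- suppressWarnings(apply_compound_scaling(c2, base))
  expect_identical(sc2$stages$n[base$stages$n == 3], c(4L, 4L))
  # constraint close to 2: no warning
  c3 <- scaling_coefficients(1, alpha = 1.2, beta = 1.1, gamma = 1.15)
  expect_lt(c3$constraint_residual, 0.1)
  expect_no_warning(apply_compound_scaling(c3, base))
  # invalid coefficients
  expect_error(scaling_coefficients(1, alpha = 0.9), ">= 1")
})

test_that("width multiplier scales conv channels proportionally", {
  cfg1 <- backbone_config("mobilenet_v1", input_resolution = 64,
                          width_multiplier = 1, n_classes = 3L)
  cfg2 <- backbone_config("mobilenet_v1", input_resolution = 64,
                          width_multiplier = 0.5, n_classes = 3L)
  m1 <- build_mobilenet_v1(cfg1, seed = 1)
  m2 <- build_mobilenet_v1(cfg2, seed = 1)
  convs <- function(m) {
    out <- integer(0)
    walk <- function(l) {
      if (l$kind == "conv") out <<- c(out, l$out_c)
      for (ch in l$children) walk(ch)
    }
    walk(m); out
  }
  expect_identical(convs(m2), pmax(1L, as.integer(round(convs(m1) * 0.5))))
})

test_that("backbone gradients agree with finite differences on tiny configs", {
  set.seed(8)
  cfg <- backbone_config("simple_cnn", input_resolution = c(16, 16),
                         base_filters = 2L, n_classes = 3L)
  m <- build_simple_cnn(cfg, seed = 4)
  jitter_params(m)
  x <- array(stats::runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  tb <- matrix(0, 3, 2); tb[1, 1] <- 1; tb[2, 2] <- 1
  lossfn <- function() {
    p <- softmax(m$fw(x, training = TRUE))
    -mean(colSums(tb * log(p)))
  }
  leafnet:::nn_zero_grads(m)
  p <- softmax(m$fw(x, training = TRUE))
  m$bw((p - tb) / ncol(tb))
  expect_lt(max_fd_rel_error(m, lossfn, n_checks = 15), 1e-3)
})
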