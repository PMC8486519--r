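# U-Net: configuration contracts, channel schedule, shape contracts,
# training behaviour on degenerate and small inputs, segmentation + crop.

test_that("input sizes must be divisible by 16", {
  expect_error(unet_config(300, 400), "divisible by 16")
  expect_s3_class(unet_config(304, 400), "unet_config")
  expect_s3_class(unet_config(64, 64), "unet_config")
})

test_that("channel schedule matches the symbolic table in f", {
  for (f in c(4L, 8L, 16L)) {
    m <- build_unet(unet_config(64, 64, 1, base_filters = f), seed = 1)
    sched <- unet_channel_schedule(m)
    expect_equal(sched[["enc1"]], 1)
    expect_equal(sched[["enc2"]], 2)
    expect_equal(sched[["enc3"]], 3)
    expect_equal(sched[["enc4"]], 4)
    expect_equal(sched[["bottleneck"]], 5)
    expect_equal(sched[["concat1"]], 9)
    expect_equal(sched[["concat2"]], 7)
    expect_equal(sched[["concat3"]], 5)
    expect_equal(sched[["concat4"]], 3)
    expect_equal(sched[["output"]], 1)
  }
})

test_that("the bottleneck sits at 1/16 resolution with 5f channels", {
  f <- 16L
  m <- build_unet(unet_config(64, 64, 1, base_filters = f), seed = 1)
  x <- array(stats::runif(64 * 64), c(64, 64, 1, 1))
  invisible(m$fw(x, training = FALSE))
  # the bottleneck block's first conv consumed a 4x4 input
  bott_conv <- m$bott$children[[1]]
  expect_identical(bott_conv$cache$dims[1:2], c(4L, 4L))
  expect_identical(bott_conv$out_c, 5L * f)  # 80 channels at f = 16
})

test_that("segment_leaf returns a probability map of the configured size", {
  m <- build_unet(unet_config(64, 64, 1, base_filters = 8), seed = 2)
  img <- generate_leaf(synthetic_leaf_spec(0, rng_seed = 3), 80, 96)$image
  pm <- segment_leaf(m, img)
  expect_identical(dim(pm), c(64L, 64L))
  expect_true(all(pm >= 0 & pm <= 1))
  expect_identical(pm, segment_leaf(m, img))  # deterministic
})

test_that("zero-epoch training returns an empty history and untouched weights", {
  m <- build_unet(unet_config(48, 48, 1, base_filters = 4), seed = 5)
  w_before <- m$enc1$children[[1]]$params$W
  ds <- tiny_clean_dataset()
  train_unet(m, ds$images[1:4], ds$masks[1:4], epochs = 0)
  expect_identical(nrow(m$history), 0L)
  expect_identical(m$enc1$children[[1]]$params$W, w_before)
})

test_that("mismatched image/mask lists are rejected", {
  m <- build_unet(unet_config(48, 48, 1, base_filters = 4), seed = 5)
  ds <- tiny_clean_dataset()
  expect_error(train_unet(m, ds$images[1:3], ds$masks[1:2]), "aligned")
})

test_that("all-background masks drive the mean output towards zero", {
  ds <- tiny_clean_dataset()
  imgs <- ds$images[1:8]
  zero_masks <- lapply(imgs, function(im) matrix(0, nrow(im), ncol(im)))
  m <- build_unet(unet_config(48, 48, 1, base_filters = 4), seed = 6)
  train_unet(m, imgs, zero_masks, epochs = 8, batch_size = 4, seed = 6)
  pm <- segment_leaf(m, imgs[[1]])
  expect_lt(mean(pm), 0.1)
})

test_that("training loss decreases over a window on clean data", {
  ds <- tiny_clean_dataset()
  m <- build_unet(unet_config(48, 48, 1, base_filters = 4), seed = 7)
  train_unet(m, ds$images, ds$masks, epochs = 8, batch_size = 6, seed = 7)
  h <- m$history
  expect_identical(nrow(h), 8L)
  expect_lt(mean(utils::tail(h$loss, 3)), mean(utils::head(h$loss, 3)))
})

test_that("unet_crop returns a leaf-centred sub-image on a trained model", {
  ds <- tiny_clean_dataset()
  m <- build_unet(unet_config(48, 48, 1, base_filters = 4), seed = 8)
  train_unet(m, ds$images, ds$masks, epochs = 10, batch_size = 6, seed = 8)
  img <- ds$images[[1]]
  cropped <- unet_crop(m, img, threshold = 0.5, margin = 0.05)
  expect_lte(nrow(cropped), nrow(img))
  expect_lte(ncol(cropped), ncol(img))
  expect_gt(length(cropped), 0)
})

test_that("U-Net gradients agree with finite differences on a tiny config", {
  set.seed(21)
  m <- build_unet(unet_config(16, 16, 1, base_filters = 2,
                              dropout_rate = 0), seed = 9)
  jitter_params(m)
  x <- array(stats::runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array((stats::runif(16 * 16 * 2) > 0.5) * 1, c(16, 16, 1, 2))
  lossfn <- function() {
    z <- m$fw(x, training = TRUE)
    p <- 1 / (1 + exp(-z))
    -mean(y * log(p + 1e-9) + (1 - y) * log(1 - p + 1e-9))
  }
  leafnet:::nn_zero_grads(m)
  z <- m$fw(x, training = TRUE)
  p <- 1 / (1 + exp(-z))
  invisible(m$bw((p - y) / length(y)))
  expect_lt(max_fd_rel_error(m, lossfn, n_checks = 15), 1e-3)
})
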