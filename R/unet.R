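# U-Net encoder-decoder for leaf-vs-background segmentation.
#
# Channel schedule (in units of the base filter count f): encoder blocks
# f, 2f, 3f, 4f with 2x2/stride-2 max-pooling between them, bottleneck 5f,
# decoder with 2x nearest upsampling and skip concatenations of merged
# widths 9f, 7f, 5f, 3f, dropout after the 4f and 5f blocks, and a final
# 1x1 convolution to a single-channel sigmoid leaf-probability map. All
# hidden activations are ReLU; each block is two 3x3 convolutions.

#' U-Net configuration
#'
#' @param input_height,input_width Input size in pixels; each must be
#'   divisible by 16 (four stride-2 poolings). The default 304 x 400
#'   greyscale input is the working resolution for photographic leaves;
#'   tests use small square inputs.
#' @param input_channels 1 (greyscale) or 3 (RGB).
#' @param base_filters f, the channel unit of the whole schedule (>= 1).
#' @param dropout_rate Dropout fraction in `[0, 1)` after the 4f and 5f
#'   blocks.
#' @return A `unet_config` list.
#' @export
unet_config <- function(input_height = 304L, input_width = 400L,
                        input_channels = 1L, base_filters = 16L,
                        dropout_rate = 0.2) {
  if (input_height %% 16 != 0 || input_width %% 16 != 0) {
    stop("input_height and input_width must each be divisible by 16 ",
         "(four 2x poolings)", call. = FALSE)
  }
  stopifnot(input_channels %in% c(1L, 3L), is_count(base_filters, 1),
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 input_channels = as.integer(input_channels),
                 base_filters = as.integer(base_filters),
                 dropout_rate = dropout_rate),
            class = "unet_config")
}

#' Build a U-Net segmentation model
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `leaf_unet` model object.
#' @examples
#' model <- build_unet(unet_config(64, 64, 1, base_filters = 4), seed = 1)
#' unet_channel_schedule(model)
#' @export
build_unet <- function(config, seed = 42L) {
  stopifnot(inherits(config, "unet_config"))
  f <- config$base_filters
  e <- with_seed(seed, {
    e <- new_layer("unet")
    dblock <- function(in_c, mid_c, out_c, dropout = 0) {
      layers <- list(ln_conv(in_c, mid_c), ln_act("relu"),
                     ln_conv(mid_c, out_c), ln_act("relu"))
      if (dropout > 0) layers <- c(layers, list(ln_dropout(dropout)))
      ln_seq(layers)
    }
    e$enc1 <- dblock(config$input_channels, f, f)
    e$enc2 <- dblock(f, 2 * f, 2 * f)
    e$enc3 <- dblock(2 * f, 3 * f, 3 * f)
    e$enc4 <- dblock(3 * f, 4 * f, 4 * f, dropout = config$dropout_rate)
    e$bott <- dblock(4 * f, 5 * f, 5 * f, dropout = config$dropout_rate)
    e$pool <- list(ln_maxpool(), ln_maxpool(), ln_maxpool(), ln_maxpool())
    e$up <- list(ln_upsample2(), ln_upsample2(), ln_upsample2(),
                 ln_upsample2())
    e$dec1 <- dblock(9 * f, 9 * f, 4 * f)
    e$dec2 <- dblock(7 * f, 3 * f, 3 * f)
    e$dec3 <- dblock(5 * f, 2 * f, 2 * f)
    e$dec4 <- dblock(3 * f, f, f)
    e$head <- ln_conv(f, 1L, k = 1L)
    e
  })
  e$children <- list(enc1 = e$enc1, enc2 = e$enc2, enc3 = e$enc3,
                     enc4 = e$enc4, bott = e$bott,
                     pool1 = e$pool[[1]], pool2 = e$pool[[2]],
                     pool3 = e$pool[[3]], pool4 = e$pool[[4]],
                     up1 = e$up[[1]], up2 = e$up[[2]], up3 = e$up[[3]],
                     up4 = e$up[[4]],
                     dec1 = e$dec1, dec2 = e$dec2, dec3 = e$dec3,
                     dec4 = e$dec4, head = e$head)
  e$config <- config
  cat_ch <- function(a, b) {
    da <- dim(a); db <- dim(b)
    out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
    out[, , seq_len(da[3]), ] <- a
    out[, , da[3] + seq_len(db[3]), ] <- b
    out
  }
  e$fw <- function(x, training = FALSE) {
    a1 <- e$enc1$fw(x, training)
    a2 <- e$enc2$fw(e$pool[[1]]$fw(a1), training)
    a3 <- e$enc3$fw(e$pool[[2]]$fw(a2), training)
    a4 <- e$enc4$fw(e$pool[[3]]$fw(a3), training)
    b <- e$bott$fw(e$pool[[4]]$fw(a4), training)
    d1 <- e$dec1$fw(cat_ch(e$up[[1]]$fw(b), a4), training)
    d2 <- e$dec2$fw(cat_ch(e$up[[2]]$fw(d1), a3), training)
    d3 <- e$dec3$fw(cat_ch(e$up[[3]]$fw(d2), a2), training)
    d4 <- e$dec4$fw(cat_ch(e$up[[4]]$fw(d3), a1), training)
    e$head$fw(d4, training)  # logits, (H, W, 1, N)
  }
  split_ch <- function(g, c_up) {
    list(up = g[, , seq_len(c_up), , drop = FALSE],
         skip = g[, , -seq_len(c_up), , drop = FALSE])
  }
  e$bw <- function(gout) {
    g <- e$dec4$bw(e$head$bw(gout))
    s4 <- split_ch(g, 2 * f)
    g <- e$dec3$bw(e$up[[4]]$bw(s4$up))
    s3 <- split_ch(g, 3 * f)
    g <- e$dec2$bw(e$up[[3]]$bw(s3$up))
    s2 <- split_ch(g, 4 * f)
    g <- e$dec1$bw(e$up[[2]]$bw(s2$up))
    s1 <- split_ch(g, 5 * f)
    g <- e$bott$bw(e$up[[1]]$bw(s1$up))
    g <- e$enc4$bw(e$pool[[4]]$bw(g) + s1$skip)
    g <- e$enc3$bw(e$pool[[3]]$bw(g) + s2$skip)
    g <- e$enc2$bw(e$pool[[2]]$bw(g) + s3$skip)
    e$enc1$bw(e$pool[[1]]$bw(g) + s4$skip)
  }
  class(e) <- c("leaf_unet", "nn_layer")
  e
}

# Named channel schedule of the built network, in multiples of f; used to
# check the architecture against its table form.
#' Channel schedule of a built U-Net
#'
#' Returns the output channel count of every convolution, plus the merged
#' concatenation widths, as multiples of the base filter count.
#' @param model A `leaf_unet`.
#' @return Named integer vector of channel multiples.
#' @export
unet_channel_schedule <- function(model) {
  f <- model$config$base_filters
  get_out <- function(block) {
    convs <- Filter(function(l) l$kind == "conv", block$children)
    vapply(convs, function(l) l$out_c, integer(1))
  }
  c(enc1 = max(get_out(model$enc1)) / f,
    enc2 = max(get_out(model$enc2)) / f,
    enc3 = max(get_out(model$enc3)) / f,
    enc4 = max(get_out(model$enc4)) / f,
    bottleneck = max(get_out(model$bott)) / f,
    concat1 = unname(model$dec1$children[[1]]$in_c / f),
    concat2 = unname(model$dec2$children[[1]]$in_c / f),
    concat3 = unname(model$dec3$children[[1]]$in_c / f),
    concat4 = unname(model$dec4$children[[1]]$in_c / f),
    output = 1 / f * model$head$out_c * f)
}

# Resize/convert an image to the model's configured input, scaled to [0, 1].
unet_prepare <- function(model, image) {
  cfg <- model$config
  img <- image
  if (cfg$input_channels == 1L) {
    img <- to_gray(img)
    img <- resize_image(img, cfg$input_height, cfg$input_width)
    dim(img) <- c(cfg$input_height, cfg$input_width, 1L)
  } else {
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3L))
    img <- resize_image(img, cfg$input_height, cfg$input_width)
  }
  img / 255
}

#' Train a U-Net on images with ground-truth masks
#'
#' Minimizes per-pixel binary cross-entropy on the sigmoid output map with
#' Adam. Images are resized/converted to the configured input internally;
#' masks are resized with nearest-neighbour sampling so they stay binary.
#'
#' @param model A `leaf_unet` from [build_unet()].
#' @param images List of H x W x 3 (or H x W) arrays on the 0-255 scale.
#' @param masks List of H x W matrices in `{0, 1}`, aligned with `images`.
#' @param epochs Number of passes over the data (0 returns the model
#'   untouched with an empty history).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Seed for shuffling and dropout.
#' @param verbose Print per-epoch loss/accuracy.
#' @return The trained model (invisibly modified in place), with a
#'   `history` data frame (epoch, loss, pixel_accuracy) attached.
#' @export
train_unet <- function(model, images, masks, epochs = 20L, batch_size = 8L,
                       lr = 1e-3, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "leaf_unet"))
  if (length(images) != length(masks) || length(images) == 0) {
    stop("`images` and `masks` must be non-empty and aligned", call. = FALSE)
  }
  cfg <- model$config
  history <- data.frame(epoch = integer(), loss = numeric(),
                        pixel_accuracy = numeric())
  if (epochs == 0) {
    model$history <- history
    return(invisible(model))
  }
  xs <- lapply(images, function(im) unet_prepare(model, im))
  ys <- lapply(masks, function(m) {
    mm <- resize_image(m, cfg$input_height, cfg$input_width,
                       interp = "nearest")
    if (!all(mm %in% c(0, 1))) stop("masks must be binary", call. = FALSE)
    mm
  })
  n <- length(xs)
  npix <- cfg$input_height * cfg$input_width
  with_seed(seed, {
    state <- nn_adam_init(model)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_agree <- 0; ep_pix <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- stack_images(xs[idx])
        yb <- stack_images(lapply(ys[idx], function(m) {
          dim(m) <- c(dim(m), 1L); m
        }))
        nn_zero_grads(model)
        z <- model$fw(xb, training = TRUE)
        p <- 1 / (1 + exp(-z))
        eps <- 1e-7
        loss <- -mean(yb * log(p + eps) + (1 - yb) * log(1 - p + eps))
        gz <- (p - yb) / length(yb)
        model$bw(gz)
        state <- nn_adam_step(state, lr)
        ep_loss <- ep_loss + loss * length(idx)
        ep_agree <- ep_agree + sum((p >= 0.5) == (yb >= 0.5))
        ep_pix <- ep_pix + length(yb)
      }
      history[nrow(history) + 1, ] <- list(ep, ep_loss / n, ep_agree / ep_pix)
      if (verbose) {
        message(sprintf("epoch %d: bce %.4f, pixel acc %.4f", ep,
                        ep_loss / n, ep_agree / ep_pix))
      }
    }
  })
  model$history <- history
  invisible(model)
}

#' Segment a leaf image into a probability map
#'
#' Resizes/converts the image to the model's configured input and returns
#' the per-pixel leaf probability map at that size.
#'
#' @param model A trained `leaf_unet`.
#' @param image H x W x 3 (or H x W) array on the 0-255 scale.
#' @return H x W matrix of probabilities in `[0, 1]` at the configured
#'   input size.
#' @export
segment_leaf <- function(model, image) {
  stopifnot(inherits(model, "leaf_unet"))
  x <- unet_prepare(model, image)
  dim(x) <- c(dim(x), 1L)
  z <- model$fw(x, training = FALSE)
  p <- 1 / (1 + exp(-z))
  matrix(p, dim(p)[1], dim(p)[2])
}

#' Segment, binarize and crop a leaf image in one step
#'
#' Runs [segment_leaf()], thresholds the map, finds the largest leaf
#' component's bounding box in the original image geometry, and crops.
#' Falls back to the full image when no foreground is detected.
#'
#' @param model A trained `leaf_unet`.
#' @param image H x W x 3 array on the 0-255 scale.
#' @param threshold Binarization threshold in `(0, 1)`.
#' @param margin Relative crop margin (see [crop_image()]).
#' @return The cropped image.
#' @export
unet_crop <- function(model, image, threshold = 0.5, margin = 0.05) {
  pm <- segment_leaf(model, image)
  mask <- binarize(pm, threshold)
  if (sum(mask) == 0) return(image)
  # map the mask back to the original image size before boxing
  mask_full <- resize_image(mask, dim(image)[1], dim(image)[2],
                            interp = "nearest")
  if (sum(mask_full) == 0) return(image)
  box <- extract_leaf_box(mask_full)
  crop_image(image, box, margin = margin)
}

#' @export
print.leaf_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<leaf_unet> input %dx%dx%d, f=%d, dropout %.2f, %s parameters\n",
    cfg$input_height, cfg$input_width, cfg$input_channels,
    cfg$base_filters, cfg$dropout_rate,
    format(nn_n_params(x), big.mark = ",")))
  invisible(x)
}
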