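# Classification backbones: simple CNN, MobileNet V1 (depthwise-separable
# stacks), MobileNet V2 (inverted residual bottlenecks), EfficientNet B0
# (MBConv with squeeze-and-excitation) and the compound-scaling transform.
#
# All builders return a `leaf_classifier`: an engine model mapping an
# input batch (H, W, 3, N) scaled to [0, 1] to a (C, N) matrix of class
# logits; softmax/fusion happen outside the model.

# MobileNet V2 bottleneck sequence: expansion t, output channels c,
# repeats n, first-block stride s.
MOBILENET_V2_ROWS <- data.frame(
  t = c(1L, 6L, 6L, 6L, 6L, 6L, 6L),
  c = c(16L, 24L, 32L, 64L, 96L, 160L, 320L),
  n = c(1L, 2L, 3L, 4L, 3L, 3L, 1L),
  s = c(1L, 2L, 2L, 2L, 1L, 2L, 1L)
)

# EfficientNet B0 MBConv stages: expansion t, kernel k, output channels c,
# repeats n, first-block stride s (strides follow the printed per-stage
# input resolutions 112,112,56,28,28,14,7).
EFFICIENTNET_B0_STAGES <- data.frame(
  t = c(1L, 6L, 6L, 6L, 6L, 6L, 6L),
  k = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
  c = c(16L, 24L, 40L, 80L, 112L, 192L, 320L),
  n = c(1L, 2L, 2L, 3L, 3L, 4L, 1L),
  s = c(1L, 2L, 2L, 1L, 2L, 2L, 1L)
)

#' Backbone configuration
#'
#' @param family One of `"simple_cnn"`, `"mobilenet_v1"`, `"mobilenet_v2"`,
#'   `"efficientnet_b0"`, `"tiny"`. `"tiny"` is a desk-scale simple CNN
#'   (f = 8 at 64 x 64) used for fast experiments and tests.
#' @param input_resolution Square input size, or `c(m, n)` for the simple
#'   CNN family.
#' @param width_multiplier Positive factor scaling every channel count
#'   (rounded, minimum 1 channel).
#' @param base_filters f for the simple CNN family.
#' @param n_classes Number of output classes C (>= 2).
#' @param stages Optional stage table override (EfficientNet family);
#'   defaults to the B0 table. Used by [apply_compound_scaling()].
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(family = c("simple_cnn", "mobilenet_v1",
                                       "mobilenet_v2", "efficientnet_b0",
                                       "tiny"),
                            input_resolution = NULL,
                            width_multiplier = 1.0,
                            base_filters = 128L,
                            n_classes = 2L,
                            stages = NULL) {
  family <- match.arg(family)
  stopifnot(width_multiplier > 0, is_count(n_classes, 2))
  if (family == "tiny") {
    family <- "simple_cnn"
    base_filters <- 8L
    if (is.null(input_resolution)) input_resolution <- c(64L, 64L)
  }
  if (is.null(input_resolution)) {
    input_resolution <- if (family == "simple_cnn") c(150L, 200L) else 224L
  }
  res <- as.integer(input_resolution)
  if (length(res) == 1) res <- c(res, res)
  if (family != "simple_cnn" && any(res %% 32 != 0)) {
    stop("input_resolution must be divisible by 32 for this family",
         call. = FALSE)
  }
  if (family == "efficientnet_b0" && is.null(stages)) {
    stages <- EFFICIENTNET_B0_STAGES
  }
  structure(list(family = family, input_resolution = res,
                 width_multiplier = width_multiplier,
                 base_filters = as.integer(base_filters),
                 n_classes = as.integer(n_classes),
                 stages = stages),
            class = "backbone_config")
}

scale_ch <- function(ch, w) max(1L, as.integer(round(ch * w)))

new_classifier <- function(body, config, extra = list()) {
  e <- new_layer("classifier")
  e$body <- body
  e$children <- list(body = body)
  e$config <- config
  for (nm in names(extra)) e[[nm]] <- extra[[nm]]
  e$fw <- function(x, training = FALSE) e$body$fw(x, training)
  e$bw <- function(gout) e$body$bw(gout)
  class(e) <- c("leaf_classifier", "nn_layer")
  e
}

#' Build the simple three-convolution CNN
#'
#' Convolutions of f, 2f, 3f channels (the first two followed by 2x2
#' max-pooling), batch normalization and ReLU in every conv block, then
#' flatten, a 2f-unit dense layer and a C-unit logit output.
#'
#' @param config A [backbone_config()] with family `"simple_cnn"` (or
#'   `"tiny"`).
#' @param seed Weight-initialization seed.
#' @return A `leaf_classifier`.
#' @export
build_simple_cnn <- function(config, seed = 42L) {
  stopifnot(inherits(config, "backbone_config"),
            config$family == "simple_cnn")
  f <- scale_ch(config$base_filters, config$width_multiplier)
  res <- config$input_resolution
  if (any(res %% 4 != 0)) {
    stop("simple CNN input must be divisible by 4 (two poolings)",
         call. = FALSE)
  }
  flat <- (res[1] %/% 4) * (res[2] %/% 4) * 3 * f
  body <- with_seed(seed, ln_seq(list(
    ln_conv(3L, f, bias = FALSE), ln_bn(f), ln_act("relu"), ln_maxpool(),
    ln_conv(f, 2L * f, bias = FALSE), ln_bn(2L * f), ln_act("relu"),
    ln_maxpool(),
    ln_conv(2L * f, 3L * f, bias = FALSE), ln_bn(3L * f), ln_act("relu"),
    ln_flatten(),
    ln_dense(flat, 2L * f), ln_act("relu"),
    ln_dense(2L * f, config$n_classes)
  )))
  new_classifier(body, config,
                 extra = list(conv_channels = c(f, 2L * f, 3L * f)))
}

#' Depthwise-separable convolution block
#'
#' A 3x3 per-channel (depthwise) convolution followed by a 1x1 pointwise
#' convolution to `out_channels`, each followed by batch normalization and
#' ReLU6 (rectified-linear clipped at 6).
#'
#' @param in_channels,out_channels Channel counts.
#' @param stride 1 or 2 (applied in the depthwise convolution).
#' @return An engine block (sequential layer).
#' @export
depthwise_separable_block <- function(in_channels, out_channels,
                                      stride = 1L) {
  stopifnot(stride %in% c(1L, 2L))
  ln_seq(list(
    ln_dwconv(in_channels, k = 3L, stride = stride),
    ln_bn(in_channels), ln_act("relu6"),
    ln_conv(in_channels, out_channels, k = 1L, bias = FALSE),
    ln_bn(out_channels), ln_act("relu6")
  ))
}

# Total weight count of the convolution kernels in a block (norm/bias
# parameters excluded).
#' @rdname depthwise_separable_block
#' @param block A block built by [depthwise_separable_block()] or
#'   [mbconv_block()].
#' @export
block_conv_param_count <- function(block) {
  slots <- nn_param_slots(block)
  sum(vapply(slots, function(s) {
    if (s$env$kind %in% c("conv", "dwconv") && s$name == "W") {
      length(s$env$params[[s$name]])
    } else 0L
  }, numeric(1)))
}

#' Build MobileNet V1
#'
#' Stem 3x3/stride-2 convolution (32 channels at multiplier 1), thirteen
#' depthwise-separable stages (including the five repeated stride-1 stages
#' at 512 channels), global average pooling and a dense classifier.
#' `layer_count()` on the result counts stem + depthwise + pointwise +
#' dense layers = 28.
#'
#' @param config A [backbone_config()] with family `"mobilenet_v1"`.
#' @param seed Weight-initialization seed.
#' @return A `leaf_classifier`.
#' @export
build_mobilenet_v1 <- function(config, seed = 42L) {
  stopifnot(inherits(config, "backbone_config"),
            config$family == "mobilenet_v1")
  w <- config$width_multiplier
  dw_strides <- c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L)
  pw_out <- c(64L, 128L, 128L, 256L, 256L, 512L, 512L, 512L, 512L, 512L,
              512L, 1024L, 1024L)
  body <- with_seed(seed, {
    ch <- scale_ch(32L, w)
    layers <- list(ln_conv(3L, ch, k = 3L, stride = 2L, bias = FALSE),
                   ln_bn(ch), ln_act("relu6"))
    for (i in seq_along(dw_strides)) {
      out <- scale_ch(pw_out[i], w)
      layers <- c(layers, list(depthwise_separable_block(ch, out,
                                                         dw_strides[i])))
      ch <- out
    }
    layers <- c(layers, list(ln_gap(), ln_dense(ch, config$n_classes)))
    ln_seq(layers)
  })
  new_classifier(body, config, extra = list(prepool_channels =
                                              scale_ch(1024L, w)))
}

#' Count of weight layers in a classifier
#'
#' Counts standard convolutions, depthwise convolutions and dense layers
#' (pooling, normalization and activations are not counted). For
#' MobileNet V1 this is stem + 13 depthwise + 13 pointwise + classifier
#' = 28, independent of the width multiplier.
#'
#' @param model A `leaf_classifier`.
#' @return Integer layer count.
#' @export
layer_count <- function(model) {
  count <- function(layer) {
    own <- as.integer(layer$kind %in% c("conv", "dwconv", "dense"))
    own + sum(vapply(layer$children, count, integer(1)), 0L)
  }
  count(model)
}

#' Mobile inverted bottleneck (MBConv) block
#'
#' 1x1 expansion convolution (ReLU6, skipped when `expansion` = 1), k x k
#' depthwise convolution (ReLU6), optional squeeze-and-excitation gate,
#' linear 1x1 projection; residual connection iff stride 1 and matching
#' channels.
#'
#' @param in_channels,out_channels Channel counts.
#' @param expansion Integer expansion factor t >= 1.
#' @param kernel_size 3 or 5.
#' @param stride 1 or 2.
#' @param se_ratio Squeeze-and-excitation bottleneck ratio in `(0, 1]`, or
#'   `NULL` for no gate.
#' @return An engine block.
#' @export
mbconv_block <- function(in_channels, out_channels, expansion = 6L,
                         kernel_size = 3L, stride = 1L, se_ratio = 0.25) {
  stopifnot(kernel_size %in% c(3L, 5L), stride %in% c(1L, 2L),
            expansion >= 1)
  if (!is.null(se_ratio)) stopifnot(se_ratio > 0, se_ratio <= 1)
  ln_inverted_residual(in_channels, out_channels, t = expansion,
                       stride = stride, k = kernel_size,
                       se_ratio = se_ratio)
}

#' Build MobileNet V2
#'
#' Stem 3x3/stride-2 convolution (32 channels), the inverted-residual
#' bottleneck sequence (t, c, n, s) = (1,16,1,1), (6,24,2,2), (6,32,3,2),
#' (6,64,4,2), (6,96,3,1), (6,160,3,2), (6,320,1,1) -- within a repeated
#' row only the first block uses the row's stride -- then a 1x1 convolution
#' to 1280 channels, global average pooling, dropout and the classifier.
#'
#' @param config A [backbone_config()] with family `"mobilenet_v2"`.
#' @param seed Weight-initialization seed.
#' @param dropout_rate Dropout before the classifier.
#' @return A `leaf_classifier` with `n_bottlenecks` = 17.
#' @export
build_mobilenet_v2 <- function(config, seed = 42L, dropout_rate = 0.2) {
  stopifnot(inherits(config, "backbone_config"),
            config$family == "mobilenet_v2")
  w <- config$width_multiplier
  rows <- MOBILENET_V2_ROWS
  n_blocks <- 0L
  body <- with_seed(seed, {
    ch <- scale_ch(32L, w)
    layers <- list(ln_conv(3L, ch, k = 3L, stride = 2L, bias = FALSE),
                   ln_bn(ch), ln_act("relu6"))
    for (r in seq_len(nrow(rows))) {
      out <- scale_ch(rows$c[r], w)
      for (rep_i in seq_len(rows$n[r])) {
        s <- if (rep_i == 1) rows$s[r] else 1L
        layers <- c(layers, list(ln_inverted_residual(
          ch, out, t = rows$t[r], stride = s, k = 3L)))
        ch <- out
        n_blocks <- n_blocks + 1L
      }
    }
    last <- if (w > 1) scale_ch(1280L, w) else 1280L
    layers <- c(layers, list(ln_conv(ch, last, k = 1L, bias = FALSE),
                             ln_bn(last), ln_act("relu6"), ln_gap(),
                             ln_dropout(dropout_rate),
                             ln_dense(last, config$n_classes)))
    ln_seq(layers)
  })
  new_classifier(body, config,
                 extra = list(prepool_channels = if (w > 1)
                   scale_ch(1280L, w) else 1280L,
                   n_bottlenecks = n_blocks))
}

#' Build EfficientNet B0
#'
#' Stem 3x3/stride-2 convolution (32 channels), the seven MBConv stages of
#' the B0 table (16x1, 24x2, 40x2, 80x3, 112x3, 192x4, 320x1 with
#' squeeze-and-excitation, kernel sizes 3/5 as tabulated), a 1x1
#' convolution to 1280 channels, pooling, dropout and the classifier.
#'
#' @param config A [backbone_config()] with family `"efficientnet_b0"`
#'   (its `stages` table may have been rescaled by
#'   [apply_compound_scaling()]).
#' @param seed Weight-initialization seed.
#' @param dropout_rate Dropout before the classifier.
#' @param se_ratio Squeeze-and-excitation ratio for every MBConv block.
#' @return A `leaf_classifier` with `n_mbconv` = 16 for the unscaled B0.
#' @export
build_efficientnet_b0 <- function(config, seed = 42L, dropout_rate = 0.2,
                                  se_ratio = 0.25) {
  stopifnot(inherits(config, "backbone_config"),
            config$family == "efficientnet_b0")
  w <- config$width_multiplier
  stages <- config$stages
  n_blocks <- 0L
  body <- with_seed(seed, {
    ch <- scale_ch(32L, w)
    layers <- list(ln_conv(3L, ch, k = 3L, stride = 2L, bias = FALSE),
                   ln_bn(ch), ln_act("relu6"))
    for (r in seq_len(nrow(stages))) {
      out <- scale_ch(stages$c[r], w)
      for (rep_i in seq_len(stages$n[r])) {
        s <- if (rep_i == 1) stages$s[r] else 1L
        layers <- c(layers, list(ln_inverted_residual(
          ch, out, t = stages$t[r], stride = s, k = stages$k[r],
          se_ratio = se_ratio)))
        ch <- out
        n_blocks <- n_blocks + 1L
      }
    }
    head_ch <- if (w > 1) scale_ch(1280L, w) else 1280L
    layers <- c(layers, list(ln_conv(ch, head_ch, k = 1L, bias = FALSE),
                             ln_bn(head_ch), ln_act("relu6"), ln_gap(),
                             ln_dropout(dropout_rate),
                             ln_dense(head_ch, config$n_classes)))
    ln_seq(layers)
  })
  new_classifier(body, config,
                 extra = list(prepool_channels = if (w > 1)
                   scale_ch(1280L, w) else 1280L,
                   n_mbconv = n_blocks))
}

#' Build a backbone from its configuration
#'
#' Dispatches to the family-specific builder.
#' @param config A [backbone_config()].
#' @param seed Weight-initialization seed.
#' @return A `leaf_classifier`.
#' @export
build_backbone <- function(config, seed = 42L) {
  switch(config$family,
         simple_cnn = build_simple_cnn(config, seed),
         mobilenet_v1 = build_mobilenet_v1(config, seed),
         mobilenet_v2 = build_mobilenet_v2(config, seed),
         efficientnet_b0 = build_efficientnet_b0(config, seed),
         stop("unknown family: ", config$family, call. = FALSE))
}

#' Compound scaling coefficients
#'
#' Depth, width and resolution scale as d = alpha^phi, omega = beta^phi,
#' r = gamma^phi under the design constraint alpha * beta^2 * gamma^2
#' approximately 2; the constraint residual is reported and warned about,
#' not enforced.
#'
#' @param phi User-chosen compound coefficient (>= 0).
#' @param alpha,beta,gamma Per-dimension scaling constants, each >= 1.
#' @return A `scaling_coefficients` list with the derived `d`, `omega`,
#'   `r` and `constraint_residual` = |alpha * beta^2 * gamma^2 - 2|.
#' @export
scaling_coefficients <- function(phi, alpha = 1.2, beta = 1.1,
                                 gamma = 1.15) {
  if (alpha < 1 || beta < 1 || gamma < 1) {
    stop("alpha, beta and gamma must each be >= 1", call. = FALSE)
  }
  stopifnot(phi >= 0)
  structure(list(phi = phi, alpha = alpha, beta = beta, gamma = gamma,
                 d = alpha^phi, omega = beta^phi, r = gamma^phi,
                 constraint_residual = abs(alpha * beta^2 * gamma^2 - 2)),
            class = "scaling_coefficients")
}

round_mult8 <- function(x) max(8L, as.integer(8 * round(x / 8)))

#' Apply compound scaling to an EfficientNet configuration
#'
#' Per-stage layer counts are multiplied by d = alpha^phi and rounded up;
#' channel counts are multiplied by omega = beta^phi and rounded to the
#' nearest multiple of 8 (minimum 8); the input resolution is multiplied
#' by r = gamma^phi and rounded. Warns when the constraint residual
#' |alpha * beta^2 * gamma^2 - 2| exceeds 0.1.
#'
#' @param coeffs A [scaling_coefficients()].
#' @param base A [backbone_config()] with family `"efficientnet_b0"`.
#' @return A new `backbone_config` with scaled `stages` and resolution.
#' @export
apply_compound_scaling <- function(coeffs, base) {
  stopifnot(inherits(coeffs, "scaling_coefficients"),
            inherits(base, "backbone_config"))
  if (base$family != "efficientnet_b0") {
    stop("compound scaling applies to the efficientnet_b0 family",
         call. = FALSE)
  }
  if (coeffs$constraint_residual > 0.1) {
    warning(sprintf(
      "alpha * beta^2 * gamma^2 = %.3f deviates from 2 by %.3f",
      coeffs$alpha * coeffs$beta^2 * coeffs$gamma^2,
      coeffs$constraint_residual))
  }
  stages <- base$stages
  stages$n <- as.integer(ceiling(stages$n * coeffs$d))
  if (coeffs$omega != 1) {
    stages$c <- vapply(stages$c * coeffs$omega, round_mult8, integer(1))
  }
  out <- base
  out$stages <- stages
  out$input_resolution <- as.integer(round(base$input_resolution *
                                             coeffs$r))
  out
}

#' @export
print.leaf_classifier <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<leaf_classifier> %s, input %dx%d, width %.2f, C=%d, %s parameters\n",
    cfg$family, cfg$input_resolution[1], cfg$input_resolution[2],
    cfg$width_multiplier, cfg$n_classes,
    format(nn_n_params(x), big.mark = ",")))
  invisible(x)
}
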