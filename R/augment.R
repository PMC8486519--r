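# Training-time augmentation: random rotation, scaling, additional
# brightness, flips and blur, applied label-preservingly and at constant
# output shape.

#' Augmentation transform specification
#'
#' All ranges are closed intervals `c(low, high)` with `low <= high`; the
#' actual rotation angle, scale factor, brightness delta and blur sigma are
#' drawn uniformly from them per call. Flips are deterministic toggles.
#' Defaults: rotation within 25 degrees, scale 0.8-1.2, brightness within
#' 40/255, blur sigma up to 1.5 px.
#'
#' @param rotation_range_deg Rotation interval in degrees.
#' @param scale_range Interval of positive scale factors.
#' @param brightness_delta Additive brightness interval on the 0-255 scale.
#' @param hflip,vflip Apply a horizontal / vertical flip.
#' @param blur_sigma_range Interval of Gaussian blur sigmas (>= 0); a drawn
#'   sigma of 0 applies no blur.
#' @return An `augmentation_spec` list.
#' @export
augmentation_spec <- function(rotation_range_deg = c(-25, 25),
                              scale_range = c(0.8, 1.2),
                              brightness_delta = c(-40, 40),
                              hflip = FALSE, vflip = FALSE,
                              blur_sigma_range = c(0, 1.5)) {
  check_interval <- function(x, name, lo_ok = -Inf) {
    if (length(x) != 2 || !is.numeric(x) || x[1] > x[2] || x[1] < lo_ok) {
      stop(sprintf("`%s` must be a closed interval c(low, high) with low <= high",
                   name), call. = FALSE)
    }
  }
  check_interval(rotation_range_deg, "rotation_range_deg")
  check_interval(scale_range, "scale_range", lo_ok = 1e-6)
  check_interval(brightness_delta, "brightness_delta")
  check_interval(blur_sigma_range, "blur_sigma_range", lo_ok = 0)
  structure(list(rotation_range_deg = rotation_range_deg,
                 scale_range = scale_range,
                 brightness_delta = brightness_delta,
                 hflip = isTRUE(hflip), vflip = isTRUE(vflip),
                 blur_sigma_range = blur_sigma_range),
            class = "augmentation_spec")
}

#' Identity augmentation (all ranges degenerate, no flips)
#' @return An `augmentation_spec` that leaves images unchanged.
#' @export
identity_augmentation <- function() {
  augmentation_spec(rotation_range_deg = c(0, 0), scale_range = c(1, 1),
                    brightness_delta = c(0, 0), hflip = FALSE, vflip = FALSE,
                    blur_sigma_range = c(0, 0))
}

#' Apply a random augmentation to an image
#'
#' Rotation and scaling act about the image centre with constant-value
#' padding (the median border intensity) and bilinear resampling; the
#' output always has the input's shape. Deterministic given `seed`.
#'
#' @param image H x W or H x W x 3 array on the 0-255 scale.
#' @param spec An [augmentation_spec()].
#' @param seed Integer seed for the sampled parameters.
#' @return The augmented image, same shape as the input.
#' @examples
#' img <- generate_leaf(synthetic_leaf_spec(1), 64, 64)$image
#' out <- augment(img, identity_augmentation(), seed = 1)
#' identical(out, img)
#' @export
augment <- function(image, spec, seed = 1L) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (length(image) == 0) stop("`image` must be non-empty", call. = FALSE)
  with_seed(seed, {
    angle <- stats::runif(1, spec$rotation_range_deg[1],
                          spec$rotation_range_deg[2])
    scale <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
    bright <- stats::runif(1, spec$brightness_delta[1],
                           spec$brightness_delta[2])
    sigma <- stats::runif(1, spec$blur_sigma_range[1],
                          spec$blur_sigma_range[2])
    out <- image
    if (angle != 0 || scale != 1) {
      out <- warp_affine(out, angle_deg = angle, scale = scale,
                         interp = "bilinear")
    }
    if (spec$hflip) {
      out <- if (length(dim(out)) == 3) {
        out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
      } else out[, rev(seq_len(ncol(out))), drop = FALSE]
    }
    if (spec$vflip) {
      out <- if (length(dim(out)) == 3) {
        out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
      } else out[rev(seq_len(nrow(out))), , drop = FALSE]
    }
    if (sigma > 0) out <- gaussian_smooth(out, sigma)
    if (bright != 0) out <- clamp(out + bright, 0, 255)
    out
  })
}
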