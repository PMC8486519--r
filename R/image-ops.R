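# Pixel-level image operations: Gaussian smoothing, affine warps, resizing,
# binarization, connected components, bounding boxes and crops.
#
# Conventions: images are H x W (grayscale) or H x W x 3 arrays on a 0-255
# scale; masks are H x W matrices in {0, 1}; pixel coordinates are 0-based,
# row-major, origin at the top-left; bounding boxes are half-open
# [x, x + w) x [y, y + h).

#' Gaussian smoothing
#'
#' Separable Gaussian low-pass filter with reflect (symmetric, edge-included)
#' boundary handling, applied per channel. Used as the preprocessing step
#' that removes small noise before segmentation.
#'
#' @param image H x W or H x W x C numeric array.
#' @param sigma Positive standard deviation in pixels. The kernel radius is
#'   `ceiling(3 * sigma)`.
#' @return An array of the same shape.
#' @examples
#' img <- matrix(stats::runif(64 * 64), 64, 64) * 255
#' sm <- gaussian_smooth(img, sigma = 2)
#' stats::var(as.numeric(sm)) < stats::var(as.numeric(img))
#' @export
gaussian_smooth <- function(image, sigma = 1.0) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a positive number", call. = FALSE)
  }
  rad <- as.integer(ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-rad, rad), sd = sigma)
  kern <- kern / sum(kern)
  smooth_1d <- function(m, along) {
    n <- dim(m)[along]
    # reflect indices: (c b a | a b c ... ) with the edge sample included
    ext <- c(rev(seq_len(min(rad, n))), seq_len(n),
             rev(seq_len(n))[seq_len(min(rad, n))])
    while (length(ext) < n + 2 * rad) ext <- c(ext[1], ext, ext[length(ext)])
    out <- 0 * m
    for (t in seq_along(kern)) {
      idx <- ext[seq_len(n) + (t - 1)]
      out <- out + kern[t] * (if (along == 1) m[idx, , drop = FALSE]
                              else m[, idx, drop = FALSE])
    }
    out
  }
  one_channel <- function(ch) smooth_1d(smooth_1d(ch, 1), 2)
  if (length(dim(image)) == 3) {
    out <- image
    for (c in seq_len(dim(image)[3])) out[, , c] <- one_channel(image[, , c])
    out
  } else {
    one_channel(image)
  }
}

# Inverse-mapped affine warp (rotation + isotropic scale about the pixel
# centre), with constant-value padding. interp = "nearest" keeps masks binary.
warp_affine <- function(image, angle_deg = 0, scale = 1,
                        interp = c("bilinear", "nearest"), pad_value = NULL) {
  interp <- match.arg(interp)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  nch <- if (length(d) == 3) d[3] else 1L
  if (is.null(pad_value)) {
    border <- if (length(d) == 3) image[c(1, H), , , drop = FALSE] else
      image[c(1, H), , drop = FALSE]
    pad_value <- stats::median(as.numeric(border))
  }
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  th <- angle_deg * pi / 180
  # inverse map: rotate by -th, scale by 1/scale
  gx <- matrix(rep(0:(W - 1), each = H), H, W) - cx
  gy <- matrix(rep(0:(H - 1), W), H, W) - cy
  sx <- (cos(th) * gx + sin(th) * gy) / scale + cx
  sy <- (-sin(th) * gx + cos(th) * gy) / scale + cy
  sample_channel <- function(ch) {
    if (interp == "nearest") {
      ix <- round(sx); iy <- round(sy)
      ok <- ix >= 0 & ix <= W - 1 & iy >= 0 & iy <= H - 1
      val <- matrix(pad_value, H, W)
      val[ok] <- ch[cbind(iy[ok] + 1, ix[ok] + 1)]
      return(val)
    }
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    val <- matrix(0, H, W); wsum <- matrix(0, H, W)
    for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
      xi <- x0 + corner[1]; yi <- y0 + corner[2]
      w <- (if (corner[1] == 0) 1 - fx else fx) *
           (if (corner[2] == 0) 1 - fy else fy)
      ok <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1 & w > 0
      v <- matrix(0, H, W)
      v[ok] <- ch[cbind(yi[ok] + 1, xi[ok] + 1)]
      val <- val + w * ok * v
      wsum <- wsum + w * ok
    }
    out <- val + (1 - wsum) * pad_value
    out
  }
  if (length(d) == 3) {
    out <- image
    for (c in seq_len(nch)) out[, , c] <- sample_channel(image[, , c])
    out
  } else {
    sample_channel(image)
  }
}

# Bilinear resize (half-pixel centre alignment); nearest for masks.
resize_image <- function(image, out_h, out_w,
                         interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (H == out_h && W == out_w) return(image)
  sy <- (seq_len(out_h) - 0.5) * H / out_h - 0.5
  sx <- (seq_len(out_w) - 0.5) * W / out_w - 0.5
  one <- function(ch) {
    if (interp == "nearest") {
      iy <- clamp(round(sy), 0, H - 1) + 1
      ix <- clamp(round(sx), 0, W - 1) + 1
      return(ch[iy, ix, drop = FALSE])
    }
    y0 <- clamp(floor(sy), 0, H - 1); y1 <- clamp(y0 + 1, 0, H - 1)
    x0 <- clamp(floor(sx), 0, W - 1); x1 <- clamp(x0 + 1, 0, W - 1)
    fy <- clamp(sy - y0, 0, 1); fx <- clamp(sx - x0, 0, 1)
    a <- ch[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - fy, 1 - fx)
    b <- ch[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, 1 - fx)
    cc <- ch[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - fy, fx)
    dd <- ch[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
    a + b + cc + dd
  }
  if (length(d) == 3) {
    out <- array(0, dim = c(out_h, out_w, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- one(image[, , c])
    out
  } else {
    one(image)
  }
}

#' Threshold a probability map into a binary mask
#'
#' `mask[i, j] = 1` iff `map[i, j] >= threshold` (ties go to foreground).
#'
#' @param map H x W matrix of probabilities in `[0, 1]`.
#' @param threshold Scalar strictly inside `(0, 1)`.
#' @return H x W matrix in `{0, 1}`.
#' @export
binarize <- function(map, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly inside (0, 1)", call. = FALSE)
  }
  (map >= threshold) * 1
}

#' Bounding box of the largest leaf component
#'
#' Labels the 8-connected foreground components of a binary mask and returns
#' the axis-aligned bounding rectangle of the largest one (by pixel area;
#' ties broken by the smallest top-left corner in (y, x) order). This is the
#' boundary-tracing step that turns a segmentation mask into a crop window.
#'
#' @param mask H x W matrix in `{0, 1}` with at least one foreground pixel.
#' @return A `bounding_box`: list with 0-based `x`, `y` and positive `w`,
#'   `h`, convention half-open `[x, x + w) x [y, y + h)`.
#' @export
extract_leaf_box <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (sum(m) == 0) stop("no leaf found: mask has no foreground pixels",
                        call. = FALSE)
  lab <- nn_label_components(m)
  areas <- tabulate(lab[lab > 0])
  best_area <- max(areas)
  cand <- which(areas == best_area)
  if (length(cand) > 1) {
    # smallest top-left (y, x) of the component bounding box wins
    keys <- vapply(cand, function(l) {
      w <- which(lab == l, arr.ind = TRUE)
      min(w[, 1]) * (ncol(m) + 1) + min(w[, 2])
    }, numeric(1))
    cand <- cand[which.min(keys)]
  }
  px <- which(lab == cand[1], arr.ind = TRUE)
  y0 <- min(px[, 1]) - 1L; y1 <- max(px[, 1]) - 1L
  x0 <- min(px[, 2]) - 1L; x1 <- max(px[, 2]) - 1L
  structure(list(x = x0, y = y0, w = x1 - x0 + 1L, h = y1 - y0 + 1L),
            class = "bounding_box")
}

#' Crop an image to a bounding box with a relative margin
#'
#' The box is dilated by `margin * max(w, h)` pixels on each side and
#' clipped to the image bounds before cropping.
#'
#' @param image H x W or H x W x C array.
#' @param box A `bounding_box` (see [extract_leaf_box()]).
#' @param margin Nonnegative fraction of `max(w, h)` added on every side.
#' @return The cropped sub-image.
#' @export
crop_image <- function(image, box, margin = 0) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (!inherits(box, "bounding_box")) stop("`box` must be a bounding_box",
                                           call. = FALSE)
  if (box$x < 0 || box$y < 0 || box$w <= 0 || box$h <= 0 ||
      box$x + box$w > W || box$y + box$h > H) {
    stop("bounding box lies outside the image", call. = FALSE)
  }
  if (margin < 0) stop("`margin` must be >= 0", call. = FALSE)
  pad <- round(margin * max(box$w, box$h))
  x0 <- max(0, box$x - pad); y0 <- max(0, box$y - pad)
  x1 <- min(W, box$x + box$w + pad); y1 <- min(H, box$y + box$h + pad)
  if (length(d) == 3) {
    image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  } else {
    image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  }
}

#' Pixel accuracy between two binary masks
#'
#' Fraction of pixels on which a predicted mask agrees with the ground
#' truth; the segmentation figure of merit used throughout.
#'
#' @param pred,truth H x W matrices in `{0, 1}` of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("`pred` and `truth` must have the same shape", call. = FALSE)
  }
  mean((pred != 0) == (truth != 0))
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> x=%d y=%d w=%d h=%d (0-based, half-open)\n",
              x$x, x$y, x$w, x$h))
  invisible(x)
}
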