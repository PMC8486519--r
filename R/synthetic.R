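# Synthetic leaf generator: labeled leaf-like images with exact ground-truth
# masks, emulating field photographs of single leaves on white, textured or
# cluttered backgrounds under varying illumination and sensor noise.
#
# Blade silhouettes are polar-parametric closed curves -- a base ellipse
# modulated by lobe and margin-serration sinusoids -- rasterized by an
# even-odd point-in-polygon fill, so the mask is exactly the set of painted
# pixels (no anti-aliased fractional pixels). A short petiole is attached at
# the blade base. The silhouette form is a deterministic function of the
# class's blade parameters; pose (rotation, position, size), illumination
# and background are per-item nuisance drawn from the spec's seed.

#' Blade shape parameters for a synthetic class
#'
#' Deterministically derives a small set of shape coefficients from a class
#' id, so distinct classes have visually separable silhouettes.
#'
#' @param class_id Integer >= 0.
#' @return List with `aspect` (minor/major axis ratio), `lobes` (lobe
#'   count), `serration_amp` (margin-serration amplitude, fraction of the
#'   radius) and `petiole_frac` (petiole length as a fraction of the blade
#'   radius).
#' @export
default_blade_params <- function(class_id) {
  stopifnot(is_count(class_id, min = 0))
  list(
    aspect = 0.45 + 0.12 * ((class_id * 2) %% 5),
    lobes = 1 + (class_id %% 5),
    serration_amp = 0.02 * ((class_id %/% 5) %% 4),
    petiole_frac = 0.15 + 0.05 * ((class_id %/% 3) %% 3)
  )
}

#' Specification of one synthetic leaf image
#'
#' @param class_id Integer >= 0; selects the blade shape via
#'   [default_blade_params()] unless `blade_params` is given.
#' @param blade_params Optional list overriding the class's shape
#'   coefficients (fields as in [default_blade_params()]).
#' @param background_kind One of `"white"`, `"textured"`, `"cluttered"`.
#' @param illumination_gain Positive scalar multiplying all pixel values.
#' @param noise_sigma Standard deviation (0-255 scale) of additive Gaussian
#'   pixel noise; 0 for a clean image.
#' @param rng_seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return A `synthetic_leaf_spec` list.
#' @export
synthetic_leaf_spec <- function(class_id, blade_params = NULL,
                                background_kind = c("white", "textured",
                                                    "cluttered"),
                                illumination_gain = 1,
                                noise_sigma = 0,
                                rng_seed = 1L) {
  background_kind <- match.arg(background_kind)
  stopifnot(is_count(class_id, min = 0),
            illumination_gain > 0, noise_sigma >= 0)
  if (is.null(blade_params)) blade_params <- default_blade_params(class_id)
  structure(list(class_id = as.integer(class_id),
                 blade_params = blade_params,
                 background_kind = background_kind,
                 illumination_gain = illumination_gain,
                 noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_leaf_spec")
}

# Closed silhouette polygon (list of x, y vertex vectors, 0-based pixel
# coordinates) for a blade + petiole; errors on degenerate parameters.
leaf_polygons <- function(bp, cx, cy, radius, angle) {
  if (is.null(bp$aspect) || bp$aspect <= 0) {
    stop("degenerate blade_params: `aspect` must be positive", call. = FALSE)
  }
  if (is.null(bp$lobes) || bp$lobes < 1) {
    stop("degenerate blade_params: `lobes` must be >= 1", call. = FALSE)
  }
  lobe_amp <- if (bp$lobes > 1) 0.35 else 0.05
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  r <- 1 + lobe_amp * cos(bp$lobes * theta) +
    bp$serration_amp * cos(24 * theta)
  if (min(r) <= 0) {
    stop("degenerate blade_params: `serration_amp` collapses the silhouette",
         call. = FALSE)
  }
  # ellipse-modulated radius, blade axis along `angle`
  bx0 <- r * cos(theta) * radius
  by0 <- r * sin(theta) * radius * bp$aspect
  rot <- function(x, y) {
    list(x = cos(angle) * x - sin(angle) * y + cx,
         y = sin(angle) * x + cos(angle) * y + cy)
  }
  blade <- rot(bx0, by0)
  # petiole: thin rectangle extending from the blade base along -axis
  pl <- bp$petiole_frac * radius
  pw <- max(1, 0.04 * radius)
  px0 <- c(-radius - pl, -radius - pl, -radius * 0.95, -radius * 0.95)
  py0 <- c(-pw, pw, pw, -pw)
  petiole <- rot(px0, py0)
  list(blade = blade, petiole = petiole)
}

# Even-odd (crossing-number) rasterization of a polygon over pixel centres.
fill_polygon <- function(poly, height, width) {
  xs <- poly$x; ys <- poly$y
  n <- length(xs)
  px <- matrix(rep(0:(width - 1), each = height), height, width)
  py <- matrix(rep(0:(height - 1), width), height, width)
  inside <- matrix(FALSE, height, width)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Generate one synthetic leaf image with its exact mask
#'
#' @param spec A [synthetic_leaf_spec()].
#' @param height,width Output size in pixels (each >= 32).
#' @return List with `image` (H x W x 3 array in `[0, 255]`), `mask`
#'   (H x W matrix in `{0, 1}`, exactly the painted leaf pixels) and
#'   `class_id`.
#' @examples
#' leaf <- generate_leaf(synthetic_leaf_spec(0), 64, 64)
#' mean(leaf$mask)  # foreground fraction
#' @export
generate_leaf <- function(spec, height = 64L, width = 64L) {
  stopifnot(inherits(spec, "synthetic_leaf_spec"),
            is_count(height, 32), is_count(width, 32))
  with_seed(spec$rng_seed, {
    H <- as.integer(height); W <- as.integer(width)
    # per-item nuisance pose
    size_frac <- stats::runif(1, 0.55, 0.85)
    angle <- stats::runif(1, 0, 2 * pi)
    cx <- (W - 1) / 2 + stats::runif(1, -0.08, 0.08) * W
    cy <- (H - 1) / 2 + stats::runif(1, -0.08, 0.08) * H
    radius <- size_frac * min(H, W) / 2
    polys <- leaf_polygons(spec$blade_params, cx, cy, radius, angle)
    mask <- fill_polygon(polys$blade, H, W) |
      fill_polygon(polys$petiole, H, W)
    if (sum(mask) < 0.01 * H * W) {
      stop("degenerate blade_params: silhouette covers < 1% of the image ",
           "(check `aspect` and the blade radius)", call. = FALSE)
    }
    # background
    img <- array(0, dim = c(H, W, 3))
    if (spec$background_kind == "white") {
      img[] <- 245
    } else {
      fx <- stats::runif(2, 0.01, 0.05); fy <- stats::runif(2, 0.01, 0.05)
      ph <- stats::runif(2, 0, 2 * pi)
      gx <- matrix(rep(0:(W - 1), each = H), H, W)
      gy <- matrix(rep(0:(H - 1), W), H, W)
      tex <- 170 + 30 * sin(2 * pi * (fx[1] * gx + fy[1] * gy) + ph[1]) +
        20 * sin(2 * pi * (fx[2] * gx - fy[2] * gy) + ph[2])
      for (c in 1:3) img[, , c] <- tex * stats::runif(1, 0.85, 1.05)
      if (spec$background_kind == "cluttered") {
        n_blobs <- sample(6:12, 1)
        for (b in seq_len(n_blobs)) {
          bx <- stats::runif(1, 0, W - 1); by <- stats::runif(1, 0, H - 1)
          brx <- stats::runif(1, 0.05, 0.2) * W
          bry <- stats::runif(1, 0.05, 0.2) * H
          col <- stats::runif(3, 40, 220)
          blob <- ((gx - bx) / brx)^2 + ((gy - by) / bry)^2 <= 1
          for (c in 1:3) {
            ch <- img[, , c]; ch[blob] <- col[c]; img[, , c] <- ch
          }
        }
      }
    }
    # paint the leaf: class-tinted green with a smooth radial shading
    base_col <- c(45 + 12 * (spec$class_id %% 3),
                  105 + 9 * (spec$class_id %% 7),
                  55 + 7 * (spec$class_id %% 5))
    gx <- matrix(rep(0:(W - 1), each = H), H, W)
    gy <- matrix(rep(0:(H - 1), W), H, W)
    dist <- sqrt((gx - cx)^2 + (gy - cy)^2)
    shade <- 1 - 0.25 * clamp(dist / (radius + 1e-9), 0, 1)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[mask] <- (base_col[c] * shade)[mask]
      img[, , c] <- ch
    }
    img <- img * spec$illumination_gain
    if (spec$noise_sigma > 0) {
      img <- img + array(stats::rnorm(length(img), sd = spec$noise_sigma),
                         dim = dim(img))
    }
    img <- clamp(img, 0, 255)
    mask_num <- matrix(0, H, W); mask_num[mask] <- 1
    fg <- mean(mask_num)
    if (fg > 0.9) stop("degenerate blade_params: silhouette covers > 90% ",
                       "of the image", call. = FALSE)
    list(image = img, mask = mask_num, class_id = spec$class_id)
  })
}

#' Generate a labeled synthetic leaf dataset
#'
#' One fixed blade shape per class; per-item nuisance (pose, illumination,
#' background texture, noise) varies with seeds derived from `master_seed`.
#'
#' @param n_classes Number of species classes (>= 2).
#' @param n_per_class Images per class (>= 2).
#' @param height,width Image size in pixels.
#' @param master_seed Integer seed controlling the whole dataset.
#' @param background_kind Background for every item (`"white"`,
#'   `"textured"` or `"cluttered"`).
#' @param noise_sigma Additive pixel-noise standard deviation (0-255 scale).
#' @param illumination_range Interval the per-item illumination gain is
#'   drawn from.
#' @return A `leaf_dataset`: list with `images`, `masks`, `labels`
#'   (0-based, contiguous), `class_registry` and an `items` data frame
#'   (id, class, seed).
#' @export
generate_dataset <- function(n_classes, n_per_class, height = 64L,
                             width = 64L, master_seed = 1L,
                             background_kind = "white",
                             noise_sigma = 3,
                             illumination_range = c(0.85, 1.15)) {
  stopifnot(is_count(n_classes, 2), is_count(n_per_class, 2))
  n <- n_classes * n_per_class
  seeds <- with_seed(master_seed, sample.int(.Machine$integer.max - 1, n))
  gains <- with_seed(master_seed + 1,
                     stats::runif(n, illumination_range[1],
                                  illumination_range[2]))
  images <- vector("list", n)
  masks <- vector("list", n)
  labels <- integer(n)
  i <- 0L
  for (k in seq_len(n_classes) - 1L) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      spec <- synthetic_leaf_spec(k, background_kind = background_kind,
                                  illumination_gain = gains[i],
                                  noise_sigma = noise_sigma,
                                  rng_seed = seeds[i])
      leaf <- generate_leaf(spec, height, width)
      images[[i]] <- leaf$image
      masks[[i]] <- leaf$mask
      labels[i] <- k
    }
  }
  structure(list(
    images = images, masks = masks, labels = labels,
    class_registry = sprintf("class_%02d", seq_len(n_classes) - 1L),
    split = NULL,
    items = data.frame(id = seq_len(n), class = labels, seed = seeds)
  ), class = "leaf_dataset")
}

#' @export
print.leaf_dataset <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<leaf_dataset> %d images (%dx%d), %d classes%s\n",
              length(x$images), d[1], d[2], length(x$class_registry),
              if (is.null(x$split)) "" else
                sprintf("; split: %s", paste(names(table(x$split)),
                                             table(x$split),
                                             sep = "=", collapse = " "))))
  invisible(x)
}
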