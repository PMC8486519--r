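# Compact reverse-mode neural-network engine.
#
# Tensors are numeric arrays with dim = c(H, W, C, N); after global pooling
# or flattening they become (features, N) matrices. Every layer is an
# environment holding its parameters, accumulated gradients and a forward
# cache, so a model is a tree of mutable layer environments. Convolution and
# pooling inner loops live in src/nn_kernels.cpp.

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- list()
  e$grads <- list()
  e$children <- list()
  class(e) <- "nn_layer"
  e
}

he_init <- function(n, fan_in) {
  stats::rnorm(n, mean = 0, sd = sqrt(2 / fan_in))
}

# Standard convolution, square kernel, symmetric zero padding (k-1)/2 when
# pad = "same". Weight dim c(k, k, in_c, out_c).
ln_conv <- function(in_c, out_c, k = 3L, stride = 1L, bias = TRUE) {
  e <- new_layer("conv")
  e$k <- as.integer(k); e$stride <- as.integer(stride)
  e$pad <- as.integer((k - 1) %/% 2)
  e$in_c <- as.integer(in_c); e$out_c <- as.integer(out_c)
  e$params$W <- array(he_init(k * k * in_c * out_c, k * k * in_c),
                      dim = c(k, k, in_c, out_c))
  if (bias) e$params$b <- numeric(out_c)
  e$fw <- function(x, training = FALSE) {
    d <- dim(x)
    cols <- nn_im2col(x, d[1], d[2], d[3], d[4], e$k, e$stride, e$pad)
    Wm <- matrix(e$params$W, ncol = e$out_c)
    out <- cols %*% Wm
    if (!is.null(e$params$b)) out <- sweep(out, 2, e$params$b, "+")
    Ho <- (d[1] + 2 * e$pad - e$k) %/% e$stride + 1
    Wo <- (d[2] + 2 * e$pad - e$k) %/% e$stride + 1
    e$cache <- list(cols = cols, dims = d, Ho = Ho, Wo = Wo)
    aperm(array(out, dim = c(Ho, Wo, d[4], e$out_c)), c(1, 2, 4, 3))
  }
  e$bw <- function(gout) {
    ca <- e$cache; d <- ca$dims
    gm <- matrix(aperm(gout, c(1, 2, 4, 3)), ncol = e$out_c)
    gW <- crossprod(ca$cols, gm)
    e$grads$W <- e$grads$W + array(gW, dim = dim(e$params$W))
    if (!is.null(e$params$b)) e$grads$b <- e$grads$b + colSums(gm)
    gcols <- gm %*% t(matrix(e$params$W, ncol = e$out_c))
    nn_col2im(gcols, d[1], d[2], d[3], d[4], e$k, e$stride, e$pad)
  }
  e
}

# Depthwise convolution: one k x k filter per input channel.
ln_dwconv <- function(channels, k = 3L, stride = 1L) {
  e <- new_layer("dwconv")
  e$k <- as.integer(k); e$stride <- as.integer(stride)
  e$channels <- as.integer(channels)
  e$params$W <- array(he_init(k * k * channels, k * k), dim = c(k, k, channels))
  e$fw <- function(x, training = FALSE) {
    d <- dim(x)
    e$cache <- list(x = x, dims = d)
    nn_dwconv_fw(x, e$params$W, d[1], d[2], d[3], d[4], e$k, e$stride)
  }
  e$bw <- function(gout) {
    d <- e$cache$dims
    r <- nn_dwconv_bw(e$cache$x, e$params$W, gout, d[1], d[2], d[3], d[4],
                      e$k, e$stride)
    e$grads$W <- e$grads$W + r$gw
    r$gx
  }
  e
}

# Batch normalization over (H, W, N) per channel; running stats for inference.
ln_bn <- function(channels, momentum = 0.9, eps = 1e-5) {
  e <- new_layer("bn")
  e$channels <- as.integer(channels)
  e$momentum <- momentum; e$eps <- eps
  e$params$gamma <- rep(1, channels)
  e$params$beta <- numeric(channels)
  e$run_mean <- numeric(channels)
  e$run_var <- rep(1, channels)
  e$fw <- function(x, training = FALSE) {
    d <- dim(x); C <- d[3]
    xp <- aperm(x, c(1, 2, 4, 3))
    m <- matrix(xp, ncol = C)
    if (training) {
      mu <- colMeans(m)
      cen <- sweep(m, 2, mu)
      v <- colMeans(cen^2)
      e$run_mean <- e$momentum * e$run_mean + (1 - e$momentum) * mu
      e$run_var <- e$momentum * e$run_var + (1 - e$momentum) * v
    } else {
      mu <- e$run_mean; v <- e$run_var
      cen <- sweep(m, 2, mu)
    }
    sd_inv <- 1 / sqrt(v + e$eps)
    xhat <- sweep(cen, 2, sd_inv, "*")
    y <- sweep(sweep(xhat, 2, e$params$gamma, "*"), 2, e$params$beta, "+")
    e$cache <- list(xhat = xhat, sd_inv = sd_inv, dims = d, training = training)
    aperm(array(y, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  }
  e$bw <- function(gout) {
    ca <- e$cache; d <- ca$dims; C <- d[3]
    gm <- matrix(aperm(gout, c(1, 2, 4, 3)), ncol = C)
    e$grads$gamma <- e$grads$gamma + colSums(gm * ca$xhat)
    e$grads$beta <- e$grads$beta + colSums(gm)
    gxhat <- sweep(gm, 2, e$params$gamma, "*")
    if (ca$training) {
      n <- nrow(gm)
      t1 <- sweep(gxhat, 2, colMeans(gxhat))
      t2 <- sweep(ca$xhat, 2, colMeans(gxhat * ca$xhat), "*")
      gx <- sweep(t1 - t2, 2, ca$sd_inv, "*")
    } else {
      gx <- sweep(gxhat, 2, ca$sd_inv, "*")
    }
    aperm(array(gx, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  }
  e
}

# Elementwise activations; work on arrays and matrices alike.
ln_act <- function(type = c("relu", "relu6", "sigmoid")) {
  type <- match.arg(type)
  e <- new_layer(paste0("act_", type))
  e$fw <- function(x, training = FALSE) {
    y <- switch(type,
      relu = pmax(x, 0),
      relu6 = pmin(pmax(x, 0), 6),
      sigmoid = 1 / (1 + exp(-x)))
    if (!is.null(dim(x))) dim(y) <- dim(x)
    e$cache <- list(x = x, y = y)
    y
  }
  e$bw <- function(gout) {
    ca <- e$cache
    g <- switch(type,
      relu = gout * (ca$x > 0),
      relu6 = gout * (ca$x > 0 & ca$x < 6),
      sigmoid = gout * ca$y * (1 - ca$y))
    if (!is.null(dim(ca$x))) dim(g) <- dim(ca$x)
    g
  }
  e
}

ln_maxpool <- function() {
  e <- new_layer("maxpool")
  e$fw <- function(x, training = FALSE) {
    d <- dim(x)
    r <- nn_maxpool2_fw(x, d[1], d[2], d[3], d[4])
    e$cache <- list(idx = r$idx, dims = d)
    r$out
  }
  e$bw <- function(gout) {
    d <- e$cache$dims
    nn_maxpool2_bw(e$cache$idx, gout, d[1], d[2], d[3], d[4])
  }
  e
}

# 2x nearest-neighbour upsampling.
ln_upsample2 <- function() {
  e <- new_layer("upsample2")
  e$fw <- function(x, training = FALSE) {
    d <- dim(x)
    e$cache <- list(dims = d)
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
      drop = FALSE]
  }
  e$bw <- function(gout) {
    d <- e$cache$dims
    H2 <- 2 * d[1]; W2 <- 2 * d[2]
    oi <- seq(1, H2, by = 2); oj <- seq(1, W2, by = 2)
    gout[oi, oj, , , drop = FALSE] + gout[oi + 1, oj, , , drop = FALSE] +
      gout[oi, oj + 1, , , drop = FALSE] + gout[oi + 1, oj + 1, , , drop = FALSE]
  }
  e
}

# Global average pooling: (H, W, C, N) -> (C, N).
ln_gap <- function() {
  e <- new_layer("gap")
  e$fw <- function(x, training = FALSE) {
    d <- dim(x)
    e$cache <- list(dims = d)
    matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
  }
  e$bw <- function(gout) {
    d <- e$cache$dims
    npix <- d[1] * d[2]
    array(rep(as.numeric(gout), each = npix) / npix, dim = d)
  }
  e
}

ln_flatten <- function() {
  e <- new_layer("flatten")
  e$fw <- function(x, training = FALSE) {
    d <- dim(x)
    e$cache <- list(dims = d)
    matrix(x, ncol = d[4])
  }
  e$bw <- function(gout) {
    array(gout, dim = e$cache$dims)
  }
  e
}

ln_dense <- function(in_f, out_f, bias = TRUE) {
  e <- new_layer("dense")
  e$in_f <- as.integer(in_f); e$out_f <- as.integer(out_f)
  e$params$W <- matrix(he_init(out_f * in_f, in_f), nrow = out_f)
  if (bias) e$params$b <- numeric(out_f)
  e$fw <- function(x, training = FALSE) {
    e$cache <- list(x = x)
    y <- e$params$W %*% x
    if (!is.null(e$params$b)) y <- y + e$params$b
    y
  }
  e$bw <- function(gout) {
    e$grads$W <- e$grads$W + tcrossprod(gout, e$cache$x)
    if (!is.null(e$params$b)) e$grads$b <- e$grads$b + rowSums(gout)
    crossprod(e$params$W, gout)
  }
  e
}

# Inverted dropout; identity at inference. Uses the session RNG stream so
# training is reproducible under a seed.
ln_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  e <- new_layer("dropout")
  e$rate <- rate
  e$fw <- function(x, training = FALSE) {
    if (!training || e$rate == 0) {
      e$cache <- list(mask = NULL)
      return(x)
    }
    mask <- (stats::runif(length(x)) >= e$rate) / (1 - e$rate)
    if (!is.null(dim(x))) dim(mask) <- dim(x)
    e$cache <- list(mask = mask)
    x * mask
  }
  e$bw <- function(gout) {
    if (is.null(e$cache$mask)) gout else gout * e$cache$mask
  }
  e
}

# Squeeze-and-excitation gate: global pool -> bottleneck dense (ReLU) ->
# dense back (sigmoid) -> channel-wise rescaling of the input.
ln_se <- function(channels, se_ratio = 0.25) {
  stopifnot(se_ratio > 0, se_ratio <= 1)
  e <- new_layer("se")
  mid <- max(1L, as.integer(ceiling(channels * se_ratio)))
  e$channels <- as.integer(channels)
  e$fc1 <- ln_dense(channels, mid)
  e$fc2 <- ln_dense(mid, channels)
  e$children <- list(fc1 = e$fc1, fc2 = e$fc2)
  e$fw <- function(x, training = FALSE) {
    d <- dim(x)
    s <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), nrow = d[3])
    h <- pmax(e$fc1$fw(s, training), 0)
    z <- e$fc2$fw(h, training)
    g <- 1 / (1 + exp(-z))
    gate <- aperm(array(rep(as.numeric(g), each = d[1] * d[2]),
                        dim = c(d[1], d[2], d[3], d[4])), c(1, 2, 3, 4))
    e$cache <- list(x = x, dims = d, h = h, g = g, gate = gate)
    x * gate
  }
  e$bw <- function(gout) {
    ca <- e$cache; d <- ca$dims
    gx1 <- gout * ca$gate
    # gradient into the per-channel gate
    gg <- matrix(colSums(matrix(gout * ca$x, nrow = d[1] * d[2])), nrow = d[3])
    gz <- gg * ca$g * (1 - ca$g)
    gh <- e$fc2$bw(gz)
    gh <- gh * (ca$h > 0)
    gs <- e$fc1$bw(gh)
    npix <- d[1] * d[2]
    gx2 <- array(rep(as.numeric(gs), each = npix) / npix, dim = d)
    gx1 + gx2
  }
  e
}

# Sequential container.
ln_seq <- function(layers) {
  e <- new_layer("seq")
  e$children <- layers
  e$fw <- function(x, training = FALSE) {
    for (l in e$children) x <- l$fw(x, training)
    x
  }
  e$bw <- function(gout) {
    for (l in rev(e$children)) gout <- l$bw(gout)
    gout
  }
  e
}

# Inverted residual bottleneck: 1x1 expansion (skipped when t = 1), depthwise
# k x k, optional squeeze-excitation, linear 1x1 projection; the skip
# connection exists only when stride = 1 and in_c = out_c.
ln_inverted_residual <- function(in_c, out_c, t = 6L, stride = 1L, k = 3L,
                                 se_ratio = NULL) {
  e <- new_layer("inv_residual")
  mid <- as.integer(in_c * t)
  e$use_skip <- (stride == 1L && in_c == out_c)
  layers <- list()
  if (t != 1L) {
    layers <- c(layers, list(ln_conv(in_c, mid, k = 1L, bias = FALSE),
                             ln_bn(mid), ln_act("relu6")))
  }
  layers <- c(layers, list(ln_dwconv(mid, k = k, stride = stride),
                           ln_bn(mid), ln_act("relu6")))
  if (!is.null(se_ratio)) layers <- c(layers, list(ln_se(mid, se_ratio)))
  layers <- c(layers, list(ln_conv(mid, out_c, k = 1L, bias = FALSE),
                           ln_bn(out_c)))
  e$body <- ln_seq(layers)
  e$children <- list(body = e$body)
  e$in_c <- as.integer(in_c); e$out_c <- as.integer(out_c)
  e$t <- as.integer(t); e$stride <- as.integer(stride)
  e$fw <- function(x, training = FALSE) {
    y <- e$body$fw(x, training)
    if (e$use_skip) y <- y + x
    y
  }
  e$bw <- function(gout) {
    g <- e$body$bw(gout)
    if (e$use_skip) g <- g + gout
    g
  }
  e
}

# --- parameter bookkeeping -------------------------------------------------

nn_zero_grads <- function(layer) {
  for (nm in names(layer$params)) {
    p <- layer$params[[nm]]
    g <- array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
    if (is.null(dim(p))) g <- as.numeric(g)
    layer$grads[[nm]] <- g
  }
  for (ch in layer$children) nn_zero_grads(ch)
  invisible(NULL)
}

# Flat list of parameter slots: each element list(env, name, path).
nn_param_slots <- function(layer, path = "root") {
  out <- list()
  for (nm in names(layer$params)) {
    out[[length(out) + 1L]] <- list(env = layer, name = nm,
                                    path = paste(path, nm, sep = "/"))
  }
  chn <- names(layer$children)
  for (i in seq_along(layer$children)) {
    tag <- if (!is.null(chn) && nzchar(chn[i])) chn[i] else as.character(i)
    out <- c(out, nn_param_slots(layer$children[[i]],
                                 paste(path, tag, sep = "/")))
  }
  out
}

nn_n_params <- function(layer) {
  sum(vapply(nn_param_slots(layer),
             function(s) length(s$env$params[[s$name]]), numeric(1)))
}

# --- Adam optimizer with optional triangular cyclic learning rate ----------

nn_adam_init <- function(layer) {
  slots <- nn_param_slots(layer)
  list(slots = slots,
       m = lapply(slots, function(s) 0 * s$env$params[[s$name]]),
       v = lapply(slots, function(s) 0 * s$env$params[[s$name]]),
       t = 0L)
}

nn_adam_step <- function(state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(state$slots)) {
    s <- state$slots[[i]]
    g <- s$env$grads[[s$name]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    s$env$params[[s$name]] <- s$env$params[[s$name]] -
      lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Triangular cyclic learning rate
#'
#' Linear ramp from `lr_min` up to `lr_max` and back over `cycle_steps`
#' optimizer steps, repeating; the schedule used for Adam during training.
#'
#' @param step 1-based optimizer step.
#' @param lr_min,lr_max Bounds of the learning-rate triangle.
#' @param cycle_steps Steps in one full up-down cycle (>= 2).
#' @return The learning rate at `step`.
#' @export
cyclic_lr <- function(step, lr_min = 1e-5, lr_max = 1e-3, cycle_steps = 200L) {
  stopifnot(lr_min <= lr_max, cycle_steps >= 2)
  pos <- ((step - 1) %% cycle_steps) / cycle_steps  # in [0, 1)
  frac <- 1 - abs(2 * pos - 1)                      # triangle: 0 -> 1 -> 0
  lr_min + (lr_max - lr_min) * frac
}
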