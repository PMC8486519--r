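# ggplot2 helpers for training histories and segmentation results.

#' Plot a multiloss training history
#'
#' Loss components L1-L4 and kappa per epoch, plus train/validation
#' accuracy on a second panel-worth of lines.
#'
#' @param history The `history` data frame attached by
#'   [train_multimodel()].
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  stopifnot(is.data.frame(history), nrow(history) > 0)
  comp <- c("L1", "L2", "L3", "L4", "kappa")
  long <- do.call(rbind, lapply(comp, function(cc) {
    data.frame(epoch = history$epoch, component = cc,
               value = history[[cc]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss component",
                  title = "Joint multiloss training") +
    ggplot2::theme_minimal()
}

#' Plot a segmentation result
#'
#' Grayscale image with the predicted mask boundary region highlighted.
#'
#' @param image H x W x 3 (or H x W) array on the 0-255 scale.
#' @param mask H x W matrix in `{0, 1}` (resized to the image if needed).
#' @return A ggplot object.
#' @export
plot_segmentation <- function(image, mask) {
  g <- to_gray(image)
  if (!identical(dim(mask), dim(g))) {
    mask <- resize_image(mask, nrow(g), ncol(g), interp = "nearest")
  }
  df <- data.frame(
    x = rep(seq_len(ncol(g)), each = nrow(g)),
    y = rep(rev(seq_len(nrow(g))), ncol(g)),
    intensity = as.numeric(g),
    leaf = as.numeric(mask) > 0
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = df[df$leaf, ], colour = "#31a354",
                        size = 0.1, alpha = 0.25) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Leaf segmentation")
}
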