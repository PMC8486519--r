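# Dataset and image I/O. Images are PNG on disk; masks are single-channel
# PNG with values {0, 255}; a CSV manifest records id, class and seed.

#' Write an image (0-255 array) as PNG
#' @param image H x W or H x W x 3 array on the 0-255 scale.
#' @param path Output file.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp(image / 255, 0, 1), path)
}

#' Read a PNG as a 0-255 array
#' @param path PNG file.
#' @return H x W (grayscale) or H x W x 3 array on the 0-255 scale.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img * 255
}

#' Write a probability map as 16-bit PNG
#' @param map H x W matrix in `[0, 1]`.
#' @param path Output file.
#' @export
write_prob_map <- function(map, path) {
  png::writePNG(clamp(map, 0, 1), path, dpi = NULL, asp = NULL)
}

#' Write a leaf dataset to a directory tree
#'
#' Layout: `root/<class_name>/<id>.png`, masks under `root/masks/<id>.png`
#' (values 0/255), and `root/manifest.csv` with columns id, class, seed.
#'
#' @param ds A `leaf_dataset`.
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(ds, root) {
  stopifnot(inherits(ds, "leaf_dataset"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), showWarnings = FALSE)
  for (i in seq_along(ds$images)) {
    cls <- ds$class_registry[ds$labels[i] + 1]
    dir.create(file.path(root, cls), showWarnings = FALSE)
    id <- sprintf("%05d", i)
    write_image_png(ds$images[[i]], file.path(root, cls,
                                              paste0(id, ".png")))
    if (!is.null(ds$masks[[i]])) {
      png::writePNG(ds$masks[[i]], file.path(root, "masks",
                                             paste0(id, ".png")))
    }
  }
  utils::write.csv(ds$items, file.path(root, "manifest.csv"),
                   row.names = FALSE)
  invisible(root)
}

#' Read a leaf dataset from a directory tree
#'
#' Expects per-class subdirectories of PNG/JPEG images (the layout written
#' by [write_dataset()]); masks and the manifest are optional.
#'
#' @param root Dataset directory.
#' @return A `leaf_dataset` (masks `NULL` when absent).
#' @export
read_dataset <- function(root) {
  classes <- sort(setdiff(list.dirs(root, recursive = FALSE,
                                    full.names = FALSE), "masks"))
  if (length(classes) == 0) stop("no class subdirectories in ", root,
                                 call. = FALSE)
  images <- list(); masks <- list(); labels <- integer(0); ids <- character(0)
  for (k in seq_along(classes)) {
    files <- list.files(file.path(root, classes[k]),
                        pattern = "\\.(png|PNG)$", full.names = TRUE)
    for (f in files) {
      img <- read_image_png(f)
      if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3L))
      images[[length(images) + 1]] <- img
      labels <- c(labels, k - 1L)
      id <- sub("\\.png$", "", basename(f), ignore.case = TRUE)
      ids <- c(ids, id)
      mf <- file.path(root, "masks", paste0(id, ".png"))
      masks[[length(masks) + 1]] <- if (file.exists(mf)) {
        m <- read_image_png(mf)
        if (length(dim(m)) == 3) m <- m[, , 1]
        (m >= 128) * 1
      } else NULL
    }
  }
  structure(list(images = images, masks = masks, labels = labels,
                 class_registry = classes, split = NULL,
                 items = data.frame(id = ids, class = labels,
                                    seed = NA_integer_)),
            class = "leaf_dataset")
}
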