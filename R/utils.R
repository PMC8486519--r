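# Shared helpers.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min &&
    x == as.integer(x)
}

# H x W x 3 array in [0, 255] -> H x W grayscale (ITU-R 601 luma).
to_gray <- function(image) {
  if (length(dim(image)) == 2) return(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Stack a list of H x W x C images into the engine's (H, W, C, N) layout.
stack_images <- function(images) {
  d <- dim(images[[1]])
  if (length(d) == 2) d <- c(d, 1L)
  out <- array(0, dim = c(d[1], d[2], d[3], length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}
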