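# Gaussian smoothing, binarization, connected components / bounding boxes,
# crops and pixel accuracy.

test_that("constant images are fixed points of Gaussian smoothing", {
  img <- array(123.4, dim = c(40, 40, 3))
  expect_equal(gaussian_smooth(img, 2), img, tolerance = 1e-12)
})

test_that("an impulse spreads symmetrically and loses peak height", {
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  sm <- gaussian_smooth(img, 1)
  expect_lt(sm[17, 17], 1)
  expect_equal(sm, sm[33:1, ], tolerance = 1e-12)  # vertical symmetry
  expect_equal(sm, sm[, 33:1], tolerance = 1e-12)  # horizontal symmetry
  expect_equal(sum(sm), 1, tolerance = 1e-9)       # mass preserved
})

test_that("smoothing reduces white-noise variance", {
  set.seed(4)
  img <- matrix(stats::rnorm(64 * 64, 128, 30), 64, 64)
  sm <- gaussian_smooth(img, 2)
  expect_lt(stats::var(as.numeric(sm)), stats::var(as.numeric(img)))
})

test_that("sigma must be positive", {
  expect_error(gaussian_smooth(matrix(0, 4, 4), 0), "positive")
  expect_error(gaussian_smooth(matrix(0, 4, 4), -1), "positive")
})

test_that("binarize applies the >= threshold convention", {
  expect_true(all(binarize(matrix(0.9, 4, 4), 0.5) == 1))
  expect_true(all(binarize(matrix(0.5, 4, 4), 0.5) == 1))  # tie rule
  cb <- matrix(c(0.2, 0.8), 4, 4)
  expect_identical(binarize(cb, 0.5), (cb >= 0.5) * 1)
  expect_error(binarize(matrix(0.5, 2, 2), 0), "\\(0, 1\\)")
  expect_error(binarize(matrix(0.5, 2, 2), 1), "\\(0, 1\\)")
})

test_that("extract_leaf_box handles full and rectangular masks exactly", {
  m <- matrix(1, 10, 20)
  b <- extract_leaf_box(m)
  expect_equal(unclass(b)[c("x", "y", "w", "h")],
               list(x = 0L, y = 0L, w = 20L, h = 10L))
  m2 <- matrix(0, 40, 40)
  m2[11:20, 6:25] <- 1  # rows 10-19, cols 5-24 (0-based)
  b2 <- extract_leaf_box(m2)
  expect_equal(unclass(b2)[c("x", "y", "w", "h")],
               list(x = 5L, y = 10L, w = 20L, h = 10L))
})

test_that("the largest 8-connected component wins, matching a brute-force scan", {
  # brute-force labeling oracle: BFS flood fill over 8-neighbourhoods
  bf_largest_box <- function(m) {
    H <- nrow(m); W <- ncol(m)
    seen <- matrix(FALSE, H, W)
    best <- NULL; best_area <- -1; best_key <- Inf
    for (j in seq_len(W)) for (i in seq_len(H)) {
      if (m[i, j] == 0 || seen[i, j]) next
      queue <- list(c(i, j)); seen[i, j] <- TRUE; comp <- matrix(0, 0, 2)
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        comp <- rbind(comp, p)
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
              m[ii, jj] == 1 && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
      area <- nrow(comp)
      key <- (min(comp[, 1]) - 1) * (W + 1) + (min(comp[, 2]) - 1)
      if (area > best_area || (area == best_area && key < best_key)) {
        best_area <- area; best_key <- key
        best <- list(x = min(comp[, 2]) - 1L, y = min(comp[, 1]) - 1L,
                     w = max(comp[, 2]) - min(comp[, 2]) + 1L,
                     h = max(comp[, 1]) - min(comp[, 1]) + 1L)
      }
    }
    best
  }
  # fixed two-component case: areas 50 and 9
  m <- matrix(0, 30, 30)
  m[3:12, 3:7] <- 1    # 10 x 5 = 50 px
  m[20:22, 20:22] <- 1 # 3 x 3 = 9 px
  b <- extract_leaf_box(m)
  expect_equal(unclass(b)[c("x", "y", "w", "h")],
               list(x = 2L, y = 2L, w = 5L, h = 10L))
  # randomized agreement with the brute-force oracle
  set.seed(12)
  for (r in 1:20) {
    mm <- matrix(as.numeric(stats::runif(24 * 24) < 0.35), 24, 24)
    if (sum(mm) == 0) next
    got <- extract_leaf_box(mm)
    want <- bf_largest_box(mm)
    expect_equal(unclass(got)[c("x", "y", "w", "h")], want)
  }
})

test_that("empty masks raise a 'no leaf found' error", {
  expect_error(extract_leaf_box(matrix(0, 8, 8)), "no leaf found")
})

test_that("crop_image honours margins and clips to bounds", {
  img <- array(seq_len(40 * 50 * 3), dim = c(40, 50, 3))
  full <- structure(list(x = 0L, y = 0L, w = 50L, h = 40L),
                    class = "bounding_box")
  expect_identical(crop_image(img, full, 0), img)
  box <- structure(list(x = 5L, y = 10L, w = 20L, h = 10L),
                   class = "bounding_box")
  sub <- crop_image(img, box, 0)
  expect_identical(dim(sub), c(10L, 20L, 3L))
  expect_identical(sub, img[11:20, 6:25, , drop = FALSE])
  huge <- crop_image(img, box, margin = 10)
  expect_identical(huge, img)
})

test_that("pixel accuracy counts agreements", {
  m <- matrix(c(0, 1), 8, 8)
  expect_equal(pixel_accuracy(m, m), 1)
  expect_equal(pixel_accuracy(m, 1 - m), 0)
  m2 <- m; m2[1:16] <- 1 - m2[1:16]
  expect_equal(pixel_accuracy(m, m2), 0.75)
  expect_error(pixel_accuracy(m, matrix(0, 4, 4)), "same shape")
})
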