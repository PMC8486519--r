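# Synthetic leaf generator: determinism, mask exactness, class separation.

test_that("white-background, noise-free leaves have a constant background", {
  spec <- synthetic_leaf_spec(2, background_kind = "white",
                              noise_sigma = 0, rng_seed = 11)
  leaf <- generate_leaf(spec, 64, 64)
  for (ch in 1:3) {
    bg <- leaf$image[, , ch][leaf$mask == 0]
    expect_length(unique(bg), 1)
  }
  expect_identical(leaf$class_id, 2L)
})

test_that("identical spec and seed give bit-identical image and mask", {
  spec <- synthetic_leaf_spec(1, background_kind = "cluttered",
                              noise_sigma = 5, rng_seed = 77)
  a <- generate_leaf(spec, 48, 48)
  b <- generate_leaf(spec, 48, 48)
  expect_identical(a, b)
})

test_that("masks are strictly binary with sane foreground coverage", {
  for (k in 0:4) {
    leaf <- generate_leaf(synthetic_leaf_spec(k, rng_seed = k + 1), 64, 64)
    expect_true(all(leaf$mask %in% c(0, 1)))
    fg <- mean(leaf$mask)
    expect_gte(fg, 0.01)
    expect_lte(fg, 0.90)
  }
})

test_that("lobe count changes the silhouette substantially", {
  bp1 <- default_blade_params(0); bp1$lobes <- 1
  bp5 <- default_blade_params(0); bp5$lobes <- 5
  m1 <- generate_leaf(synthetic_leaf_spec(0, blade_params = bp1,
                                          rng_seed = 5), 64, 64)$mask
  m5 <- generate_leaf(synthetic_leaf_spec(0, blade_params = bp5,
                                          rng_seed = 5), 64, 64)$mask
  expect_gte(mean(m1 != m5), 0.05)
})

test_that("degenerate blade parameters raise errors naming the parameter", {
  bad <- default_blade_params(0); bad$serration_amp <- 5
  expect_error(generate_leaf(synthetic_leaf_spec(0, blade_params = bad)),
               "serration_amp")
  bad2 <- default_blade_params(0); bad2$aspect <- -1
  expect_error(generate_leaf(synthetic_leaf_spec(0, blade_params = bad2)),
               "aspect")
})

test_that("generate_dataset produces the requested counts and labels", {
  ds <- generate_dataset(2, 3, 48, 48, master_seed = 3)
  expect_length(ds$images, 6)
  expect_identical(sort(ds$labels), c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_identical(ds$class_registry, c("class_00", "class_01"))
  ds2 <- generate_dataset(5, 4, 48, 48, master_seed = 3)
  expect_length(ds2$images, 20)
})

test_that("different master seeds vary images but not the label multiset", {
  a <- generate_dataset(2, 2, 48, 48, master_seed = 1)
  b <- generate_dataset(2, 2, 48, 48, master_seed = 2)
  expect_identical(a$labels, b$labels)
  diffs <- mapply(function(x, y) !identical(x, y), a$images, b$images)
  expect_true(all(diffs))
})

test_that("mask and image stay aligned: leaf interior darker than white background", {
  ds <- tiny_clean_dataset()
  for (i in c(1, 8, 15)) {
    m <- ds$masks[[i]]
    gray <- leafnet:::to_gray(ds$images[[i]])
    # erode by requiring the full 8-neighbourhood to be foreground
    er <- m
    H <- nrow(m); W <- ncol(m)
    er[2:(H - 1), 2:(W - 1)] <-
      m[2:(H - 1), 2:(W - 1)] * m[1:(H - 2), 2:(W - 1)] *
      m[3:H, 2:(W - 1)] * m[2:(H - 1), 1:(W - 2)] * m[2:(H - 1), 3:W]
    inside <- mean(gray[er == 1])
    outside <- mean(gray[m == 0])
    expect_gt(abs(outside - inside), 3)
  }
})

test_that("datasets round-trip through the on-disk layout", {
  ds <- generate_dataset(2, 2, 48, 48, master_seed = 9)
  root <- withr::local_tempdir()
  write_dataset(ds, root)
  expect_true(file.exists(file.path(root, "manifest.csv")))
  back <- read_dataset(root)
  expect_length(back$images, 4)
  expect_identical(back$class_registry, ds$class_registry)
  expect_identical(sort(back$labels), sort(ds$labels))
  # 8-bit PNG quantization: images equal to within one grey level
  expect_lt(max(abs(back$images[[1]] - ds$images[[1]])), 1.0)
  expect_true(all(back$masks[[1]] %in% c(0, 1)))
})
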