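test_that("scene_spec validates its geometry and hue intervals", {
  expect_error(scene_spec(crop_hue_range = c(0.1, 0.3),
                          soil_hue_range = c(0.2, 0.4)), "disjoint")
  expect_error(scene_spec(illumination_amplitude = 1), "\\[0, 1\\)")
  expect_error(scene_spec(height = 0), "positive")
  expect_error(scene_spec(noise_sd = -1), ">= 0")
})

test_that("generate_scene is bit-deterministic given its seed", {
  spec <- scene_spec(seed = 42)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$mask, b$mask)
  c <- generate_scene(scene_spec(seed = 43))
  expect_false(identical(a$mask, c$mask) && identical(unclass(a$image),
                                                      unclass(c$image)))
})

test_that("a scene without plants has an all-background mask", {
  sc <- generate_scene(scene_spec(n_plants = 0, weed_count = 3, seed = 7))
  expect_true(all(sc$mask == 0))
})

test_that("crop coverage is positive and bounded by the leaf stencil areas", {
  sc <- generate_scene(scene_spec(height = 64, width = 64, n_plants = 3,
                                  seed = 11))
  frac <- mean(sc$mask)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
  ell <- attr(sc$mask, "ellipses")
  # each ellipse covers at most ~pi*(a + px)(b + px) pixel centers
  bound <- sum(pi * (ell[, "a"] + 1) * (ell[, "b"] + 1))
  expect_lte(sum(sc$mask), bound)
})

test_that("weed blobs are rendered but never labeled crop", {
  with_w <- generate_scene(scene_spec(weed_count = 4, seed = 13))
  without <- generate_scene(scene_spec(weed_count = 0, seed = 13))
  # weeds are drawn after the crop layer, so the label mask is unchanged
  expect_identical(with_w$mask, without$mask)
  # but they do change the rendered image (green pixels labeled 0)
  expect_false(identical(unclass(with_w$image), unclass(without$image)))
})

test_that("identity augmentation returns the pair unchanged", {
  sc <- generate_scene(scene_spec(seed = 3))
  out <- augment_pair(sc$image, sc$mask)
  expect_identical(unclass(out$image), unclass(sc$image))
  expect_identical(out$mask, matrix(as.integer(sc$mask), nrow(sc$mask)))
})

test_that("horizontal flip is an involution on the pair", {
  sc <- generate_scene(scene_spec(seed = 4))
  p <- augment_params(flip_h = TRUE)
  once <- augment_pair(sc$image, sc$mask, p)
  twice <- augment_pair(once$image, once$mask, p)
  expect_identical(unclass(twice$image), unclass(sc$image))
  expect_equal(twice$mask, matrix(as.integer(sc$mask), nrow(sc$mask)))
})

test_that("quarter-turn rotation equals the explicit index remap", {
  sc <- generate_scene(scene_spec(height = 20, width = 20, seed = 5))
  out <- augment_pair(sc$image, sc$mask, augment_params(rot90 = 1))
  H <- nrow(sc$mask)
  # 0-based oracle: destination (j, H - 1 - i) <- source (i, j)
  expected <- matrix(0L, ncol(sc$mask), H)
  for (i in seq_len(H)) for (j in seq_len(ncol(sc$mask)))
    expected[j, H - i + 1] <- sc$mask[i, j]
  expect_identical(out$mask, expected)
  for (ch in 1:3)
    expect_identical(out$image[, , ch][1:5, 1:5],
                     expected_img <- t(sc$image[, , ch])[, H:1][1:5, 1:5])
})

test_that("geometric transforms keep image and mask synchronized", {
  sc <- generate_scene(scene_spec(seed = 6))
  p <- augment_params(flip_h = TRUE, flip_v = TRUE, rot90 = 2)
  pair <- augment_pair(sc$image, sc$mask, p)
  # transforming the mask alone through the same exact ops must agree
  m <- sc$mask
  m <- m[, rev(seq_len(ncol(m)))]
  m <- m[rev(seq_len(nrow(m))), ]
  for (k in 1:2) m <- t(m)[, rev(seq_len(nrow(m)))]
  expect_equal(pair$mask, matrix(as.integer(m), nrow(m)))
})

test_that("masks stay exactly binary through any augmentation chain", {
  sc <- generate_scene(scene_spec(seed = 8))
  p <- augment_params(flip_v = TRUE, rot90 = 3, angle = 17.3, zoom = 1.07,
                      tx = 0.06, ty = -0.04, blur_sigma = 0.8,
                      sp_density = 0.02)
  out <- augment_pair(sc$image, sc$mask, p, seed = 2)
  expect_true(all(out$mask %in% c(0L, 1L)))
  expect_true(all(unclass(out$image) >= 0 & unclass(out$image) <= 1))
})

test_that("augment_pair rejects mismatched pairs", {
  sc <- generate_scene(scene_spec(seed = 9))
  expect_error(augment_pair(sc$image, sc$mask[-1, ]), "differ")
})

test_that("generate_dataset aligns views, masks and scene ids", {
  spec <- scene_spec(height = 16, width = 16, seed = 1)
  ds <- generate_dataset(spec, n_raw = 3, augment_to = 9, seed = 77)
  expect_length(ds, 9)
  expect_named(ds$views, c("rgb", "hsv"))
  # HSV view is derived from the augmented RGB image, exactly
  for (i in c(1, 5, 9))
    expect_identical(unclass(ds$views$hsv[[i]]),
                     unclass(rgb_to_hsv(ds$views$rgb[[i]])))
  expect_true(all(ds$scene %in% 1:3))
  expect_identical(ds$scene[1:3], 1:3)
})

test_that("generate_dataset with n_raw = augment_to = 1 is one raw triple", {
  spec <- scene_spec(height = 16, width = 16, seed = 1)
  ds <- generate_dataset(spec, n_raw = 1, augment_to = 1, seed = 5)
  expect_length(ds, 1)
  expect_true(sum(ds$masks[[1]]) > 0)
})

test_that("generate_dataset is reproducible item by item", {
  spec <- scene_spec(height = 16, width = 16, seed = 1)
  a <- generate_dataset(spec, 2, 6, seed = 123)
  b <- generate_dataset(spec, 2, 6, seed = 123)
  for (i in seq_len(6)) {
    expect_identical(unclass(a$views$rgb[[i]]), unclass(b$views$rgb[[i]]))
    expect_identical(a$masks[[i]], b$masks[[i]])
  }
})

test_that("split sizes follow floor(N r / sum r) with remainder to train", {
  ds <- split_dataset(dummy_dataset(10), ratios = c(7, 2, 1), seed = 1)
  expect_equal(sum(ds$split == "train"), 7)
  expect_equal(sum(ds$split == "val"), 2)
  expect_equal(sum(ds$split == "test"), 1)
  # remainder case: 11 items -> floor gives 7/2/1 and train absorbs the rest
  ds2 <- split_dataset(dummy_dataset(11), seed = 1)
  expect_equal(sum(ds2$split == "train"), 8)
})

test_that("splits partition the index set and are seed-reproducible", {
  a <- split_dataset(dummy_dataset(50), seed = 9)
  b <- split_dataset(dummy_dataset(50), seed = 9)
  c <- split_dataset(dummy_dataset(50), seed = 10)
  expect_identical(a$split, b$split)
  expect_false(identical(a$split, c$split))
  expect_true(all(a$split %in% c("train", "val", "test")))
})

test_that("scene-level splitting keeps augmented copies together", {
  ds <- dummy_dataset(20, scene = rep(1:5, each = 4))
  ds <- split_dataset(ds, seed = 3, by = "scene")
  for (sc in 1:5)
    expect_length(unique(ds$split[ds$scene == sc]), 1)
  expect_setequal(unique(ds$split), c("train", "val", "test"))
})
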