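test_that("weight schemes produce valid vectors", {
  expect_equal(as.numeric(make_weights("constant", 2)), c(0.5, 0.5))
  expect_equal(as.numeric(make_weights("constant", 4)), rep(0.25, 4))
  w <- make_weights("abundance", 2, abundances = c(0.1, 0.9))
  expect_equal(as.numeric(w), c(0.1, 0.9))
  r <- make_weights("random", 5, seed = 3)
  expect_true(all(r >= 0))
  expect_equal(sum(r), 1, tolerance = 1e-12)
  expect_identical(make_weights("random", 5, seed = 3), r)
})

test_that("invalid abundances and weights are rejected", {
  expect_error(make_weights("abundance", 2, abundances = c(0.2, 0.9)),
               "sum to 1")
  expect_error(make_weights("abundance", 2, abundances = c(0.5)), "fractions")
  expect_error(ensemble_loss(c(0.1, 0.2), c(0.7, 0.7)), "sum to 1")
  expect_error(ensemble_loss(c(0.1, 0.2), c(-0.5, 1.5)), "non-negative")
})

test_that("ensemble_loss is the weighted sum of member losses", {
  expect_equal(ensemble_loss(c(0.4, 0.6), make_weights("constant", 2)), 0.5)
  expect_equal(ensemble_loss(0.37, as_w <- make_weights("constant", 1)), 0.37)
  set.seed(8)
  for (k in 2:5) {
    l <- runif(k)
    w <- make_weights("random", k, seed = k)
    acc <- 0
    for (i in seq_len(k)) acc <- acc + w[i] * l[i]
    expect_equal(ensemble_loss(l, w), acc, tolerance = 1e-15)
  }
  expect_error(ensemble_loss(c(0.1, 0.2, 0.3), make_weights("constant", 2)),
               "lengths")
})

test_that("fusion is the convex combination of member maps", {
  w <- make_weights("constant", 2)
  a <- matrix(0.8, 2, 2); b <- matrix(0.4, 2, 2)
  expect_equal(fuse_predictions(list(a, b), w), matrix(0.6, 2, 2))
  # identical maps are a fixed point
  expect_equal(fuse_predictions(list(a, a), w), a)
  # k = 1 is the identity
  expect_equal(fuse_predictions(list(b), make_weights("constant", 1)), b)
  expect_error(fuse_predictions(list(a, b[1, , drop = FALSE]), w), "shapes")
})

test_that("fused probabilities stay within the member envelope", {
  set.seed(9)
  for (t in 1:10) {
    k <- sample(2:4, 1)
    maps <- lapply(seq_len(k), function(i) matrix(runif(36), 6, 6))
    w <- make_weights("random", k, seed = t)
    f <- fuse_predictions(maps, w)
    lo <- Reduce(pmin, maps); hi <- Reduce(pmax, maps)
    expect_true(all(f >= lo - 1e-12 & f <= hi + 1e-12))
  }
})

test_that("classify thresholds with ties going to crop", {
  m <- matrix(c(0.6, 0.5, 0.49, 0), 2, 2)
  expect_equal(classify(m, 0.5), matrix(c(1L, 1L, 0L, 0L), 2, 2))
  expect_true(all(classify(matrix(0, 3, 3), 0.5) == 0L))
  expect_error(classify(m, 0), "\\(0, 1\\)")
  expect_error(classify(m, 1), "\\(0, 1\\)")
})

test_that("ensemble history obeys the weighted bookkeeping identities", {
  ds <- tiny_split_dataset(n = 10, size = 16)
  cfg <- ensemble_config(k = 2, epochs = 2,
                         member = unet_config(depth = 2, base_channels = 2),
                         batch_size = 4, seed = 1)
  ens <- train_ensemble(ds, cfg)
  h <- ens$history
  # LO_j = sum_i w_i LO_ji, exactly as accumulated
  expect_equal(h$loss, drop(h$member_loss %*% as.numeric(cfg$weights)))
  # with the constant [0.5, 0.5] configuration it is the arithmetic mean
  expect_equal(h$loss, rowMeans(h$member_loss))
  expect_equal(h$accuracy, rowSums(h$member_accuracy))
  expect_equal(h$avg_loss, sum(h$loss) / cfg$epochs)
})

test_that("a k = 1 ensemble reduces to single-model training", {
  ds <- tiny_split_dataset(n = 8, size = 16)
  mcfg <- unet_config(depth = 2, base_channels = 2)
  cfg <- ensemble_config(k = 1, weights = make_weights("constant", 1),
                         epochs = 2, member = mcfg, views = "rgb",
                         batch_size = 4, seed = 7)
  ens <- train_ensemble(ds, cfg)
  tr <- segens:::dataset_subset(ds, "rgb", "train")
  va <- segens:::dataset_subset(ds, "rgb", "val")
  fit <- train_unet(tr$images, tr$masks, mcfg, epochs = 2, lr = cfg$lr,
                    batch_size = 4, seed = 7, val_images = va$images,
                    val_masks = va$masks)
  expect_identical(ens$members[[1]]$params, fit$model$params)
  expect_equal(ens$history$loss, fit$history$loss)
  img <- ds$views$rgb[[1]]
  expect_identical(predict(ens, list(rgb = img)), predict(fit$model, img))
})

test_that("jointly permuting members and weights leaves the loss unchanged", {
  ds <- tiny_split_dataset(n = 8, size = 16)
  mcfg <- unet_config(depth = 2, base_channels = 2)
  w <- make_weights("abundance", 2, abundances = c(0.3, 0.7))
  cfg_a <- ensemble_config(k = 2, weights = w, epochs = 2, member = mcfg,
                           views = c("rgb", "hsv"), batch_size = 4, seed = 2)
  cfg_b <- ensemble_config(k = 2, weights = rev(as.numeric(w)), epochs = 2,
                           member = mcfg, views = c("hsv", "rgb"),
                           batch_size = 4, seed = 2)
  ha <- train_ensemble(ds, cfg_a)$history
  hb <- train_ensemble(ds, cfg_b)$history
  expect_equal(ha$loss, hb$loss, tolerance = 1e-12)
  expect_equal(ha$member_loss, hb$member_loss[, 2:1], tolerance = 1e-12)
})

test_that("ensemble training rejects a view/member mismatch", {
  ds <- tiny_split_dataset(n = 6, size = 16)
  expect_error(
    train_ensemble(ds, ensemble_config(k = 2, views = c("rgb", "yuv"),
                                       epochs = 1)),
    "lacks")
  expect_error(ensemble_config(k = 3, views = c("rgb", "hsv")), "per member")
})

test_that("ensemble prediction derives the HSV view and fuses", {
  ds <- tiny_split_dataset(n = 6, size = 16)
  cfg <- ensemble_config(k = 2, epochs = 1,
                         member = unet_config(depth = 2, base_channels = 2),
                         batch_size = 4, seed = 3)
  ens <- train_ensemble(ds, cfg)
  img <- ds$views$rgb[[1]]
  # giving only the RGB image must equal giving both views explicitly
  p_auto <- predict(ens, img)
  p_full <- predict(ens, list(rgb = img, hsv = rgb_to_hsv(img)))
  expect_identical(p_auto, p_full)
  member <- predict(ens, img, type = "member")
  manual <- fuse_predictions(list(member[[1]][[1]], member[[2]][[1]]),
                             ens$weights)
  expect_equal(p_auto, manual, tolerance = 1e-12)
  msk <- predict(ens, img, type = "mask")
  expect_true(all(msk %in% c(0L, 1L)))
})

test_that("ensembles round-trip through checkpoint directories", {
  ds <- tiny_split_dataset(n = 6, size = 16)
  cfg <- ensemble_config(k = 2, epochs = 1,
                         member = unet_config(depth = 2, base_channels = 2),
                         batch_size = 4, seed = 4)
  ens <- train_ensemble(ds, cfg)
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  ens2 <- load_ensemble(dir)
  expect_equal(as.numeric(ens2$weights), as.numeric(ens$weights))
  expect_identical(ens2$views, ens$views)
  img <- ds$views$rgb[[2]]
  expect_identical(predict(ens, img), predict(ens2, img))
})
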