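test_that("the canonical depth-4 architecture has 23 convolutional layers", {
  layers <- unet_layers(unet_config(depth = 4, base_channels = 64))
  expect_equal(nrow(layers), 23)
  expect_equal(sum(layers$type == "conv3x3"), 18)
  expect_equal(sum(layers$type == "upconv2x2"), 4)
  expect_equal(sum(layers$type == "conv1x1"), 1)
  # encoder-decoder only: no fully connected layer anywhere
  expect_true(all(layers$type %in% c("conv3x3", "upconv2x2", "conv1x1")))
})

test_that("layer count follows the 5*depth + 3 pattern of the architecture", {
  for (d in 1:4)
    expect_equal(nrow(unet_layers(unet_config(depth = d))), 5 * d + 3)
})

test_that("channels double along the contracting path and halve expanding", {
  layers <- unet_layers(unet_config(depth = 3, base_channels = 8))
  enc_out <- layers$out_ch[layers$type == "conv3x3"][c(2, 4, 6)]
  expect_equal(enc_out, c(8, 16, 32))
  ups <- layers[layers$type == "upconv2x2", ]
  expect_equal(ups$out_ch, ups$in_ch / 2)
})

test_that("count_parameters matches both the descriptor oracle and the arrays", {
  # independent counting oracle over the layer walk
  oracle <- function(cfg) {
    l <- unet_layers(cfg)
    cells <- c(conv3x3 = 9, upconv2x2 = 4, conv1x1 = 1)[l$type]
    sum(cells * l$in_ch * l$out_ch + l$out_ch)
  }
  for (cfg in list(unet_config(1, 1), unet_config(2, 4), unet_config(3, 8))) {
    m <- build_unet(cfg, seed = 1)
    direct <- sum(vapply(m$params, function(p) length(p$W) + length(p$b), 1))
    expect_equal(count_parameters(m), oracle(cfg))
    expect_equal(count_parameters(m), direct)
  }
  expect_equal(count_parameters(build_unet(unet_config(1, 1))), 136)
})

test_that("doubling base channels roughly quadruples the parameter count", {
  r <- count_parameters(build_unet(unet_config(2, 16))) /
    count_parameters(build_unet(unet_config(2, 8)))
  expect_gt(r, 3.4)
  expect_lt(r, 4.05)
})

test_that("the GEMM convolution agrees with a direct loop-nest oracle", {
  set.seed(31)
  x <- array(rnorm(7 * 9 * 2 * 3), c(7, 9, 2, 3))
  W <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  got <- segens:::conv3_fwd(x, list(W = W, b = b))
  expect_equal(got, naive_conv3(x, W, b), tolerance = 1e-12)
})

test_that("backpropagation matches numerical finite differences", {
  set.seed(5)
  cfg <- unet_config(depth = 2, base_channels = 2)
  m <- build_unet(cfg, seed = 3)
  x <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  y <- array(rbinom(8 * 8 * 2, 1, 0.5), c(8, 8, 2))
  lossfun <- function(m) bce_loss(segens:::nn_forward(m, x)$prob, y)
  fw <- segens:::nn_forward(m, x, keep = TRUE)
  G <- segens:::nn_backward(m, fw$cache, (fw$prob - y) / length(fw$prob))
  h <- 1e-6
  for (nm in names(m$params)) {
    for (t in 1:2) {
      idx <- sample(length(m$params[[nm]]$W), 1)
      mp <- m; mp$params[[nm]]$W[idx] <- mp$params[[nm]]$W[idx] + h
      mm <- m; mm$params[[nm]]$W[idx] <- mm$params[[nm]]$W[idx] - h
      num <- (lossfun(mp) - lossfun(mm)) / (2 * h)
      expect_equal(G[[nm]]$dW[idx], num, tolerance = 1e-3)
    }
    idx <- sample(length(m$params[[nm]]$b), 1)
    mp <- m; mp$params[[nm]]$b[idx] <- mp$params[[nm]]$b[idx] + h
    mm <- m; mm$params[[nm]]$b[idx] <- mm$params[[nm]]$b[idx] - h
    num <- (lossfun(mp) - lossfun(mm)) / (2 * h)
    expect_equal(G[[nm]]$db[idx], num, tolerance = 1e-3)
  }
})

test_that("prediction preserves shape and stays in [0, 1]", {
  m <- build_unet(unet_config(depth = 3, base_channels = 4), seed = 2)
  img <- rand_rgb_tensor(64, 64, seed = 4)
  p <- predict(m, img)
  expect_equal(dim(p), c(64, 64))
  expect_true(all(p >= 0 & p <= 1))
  # non-square input divisible by 2^depth also works
  p2 <- predict(m, unclass(rand_rgb_tensor(32, 64, seed = 5)))
  expect_equal(dim(p2), c(32, 64))
})

test_that("indivisible input sizes raise an error naming the multiple", {
  m <- build_unet(unet_config(depth = 3, base_channels = 4), seed = 2)
  expect_error(predict(m, rand_rgb_tensor(30, 32, seed = 1)), "multiples of 8")
})

test_that("a zeroed output head predicts exactly 0.5 everywhere", {
  m <- build_unet(unet_config(depth = 1, base_channels = 2), seed = 7)
  m$params$head$W[] <- 0
  m$params$head$b[] <- 0
  p <- predict(m, rand_rgb_tensor(8, 8, seed = 2))
  expect_true(all(p == 0.5))
})

test_that("the forward pass is deterministic and batching does not change it", {
  m <- build_unet(unet_config(depth = 2, base_channels = 4), seed = 9)
  imgs <- lapply(1:3, function(i) rand_rgb_tensor(16, 16, seed = i))
  one_by_one <- lapply(imgs, function(im) predict(m, im))
  batched <- predict(m, imgs, batch_size = 3)
  expect_equal(one_by_one, batched, tolerance = 1e-12)
  expect_identical(predict(m, imgs[[1]]), predict(m, imgs[[1]]))
})

test_that("initialization is seed-reproducible", {
  a <- build_unet(unet_config(2, 4), seed = 11)
  b <- build_unet(unet_config(2, 4), seed = 11)
  c <- build_unet(unet_config(2, 4), seed = 12)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("model checkpoints round-trip through disk", {
  m <- build_unet(unet_config(2, 4), seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  img <- rand_rgb_tensor(16, 16, seed = 3)
  expect_identical(predict(m, img), predict(m2, img))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(), bad)
  expect_error(load_model(bad), "checkpoint")
})
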