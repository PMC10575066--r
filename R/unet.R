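#' UNet architecture configuration
#'
#' Describes a UNet: `depth` down-sampling stages of double 3x3
#' convolutions (ReLU) followed by 2x2 max pooling, channels doubling at
#' each stage; a double-conv bottleneck; a symmetric expanding path of 2x2
#' up-convolutions (halving channels), concatenation with the matching
#' encoder feature map and double convs; and a final 1x1 convolution to one
#' channel with sigmoid activation.  There is no fully connected layer.
#' Convolutions are zero-padded ("same"), so the output mask has the input
#' size; inputs must have height and width divisible by `2^depth`.
#'
#' @param depth number of down-sampling stages (>= 1; 4 gives the canonical
#'   23-convolutional-layer UNet).
#' @param base_channels feature channels of the first stage.
#' @param in_channels input channels (3 for RGB or HSV).
#' @return A `unet_config`.
#' @export
unet_config <- function(depth = 4, base_channels = 16, in_channels = 3) {
  if (!is_count(depth, 1)) stop_input("`depth` must be a positive integer")
  if (!is_count(base_channels, 1)) stop_input("`base_channels` must be a positive integer")
  if (!is_count(in_channels, 1)) stop_input("`in_channels` must be a positive integer")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels)),
            class = "unet_config")
}

#' Walk the UNet architecture as a layer table
#'
#' Enumerates every weight-bearing layer (3x3 convolutions, 2x2
#' up-convolutions and the 1x1 output head) in forward order with its
#' channel counts.  `count_parameters()` and the layer-count checks are
#' pure functions of this descriptor.
#'
#' @param cfg a [unet_config].
#' @return A data frame with columns `name`, `type`, `in_ch`, `out_ch`,
#'   `activation`.
#' @examples
#' nrow(unet_layers(unet_config(depth = 4)))  # 23 convolutional layers
#' @export
unet_layers <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- function(i) cfg$base_channels * 2L^(i - 1L)   # encoder stage width
  rows <- list()
  add <- function(name, type, cin, cout, act)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, type = type,
                                             in_ch = cin, out_ch = cout,
                                             activation = act)
  cin <- cfg$in_channels
  for (i in seq_len(cfg$depth)) {
    add(paste0("e", i, "c1"), "conv3x3", cin, ch(i), "relu")
    add(paste0("e", i, "c2"), "conv3x3", ch(i), ch(i), "relu")
    cin <- ch(i)
  }
  add("bc1", "conv3x3", ch(cfg$depth), ch(cfg$depth + 1L), "relu")
  add("bc2", "conv3x3", ch(cfg$depth + 1L), ch(cfg$depth + 1L), "relu")
  for (i in rev(seq_len(cfg$depth))) {
    add(paste0("d", i, "u"), "upconv2x2", ch(i + 1L), ch(i), "linear")
    add(paste0("d", i, "c1"), "conv3x3", 2L * ch(i), ch(i), "relu")
    add(paste0("d", i, "c2"), "conv3x3", ch(i), ch(i), "relu")
  }
  add("head", "conv1x1", ch(1L), 1L, "sigmoid")
  do.call(rbind, rows)
}

kernel_cells <- c(conv3x3 = 9L, upconv2x2 = 4L, conv1x1 = 1L)

#' Build a UNet model with freshly initialized parameters
#'
#' Convolution weights use He fan-in scaling (`sd = sqrt(2 / (k * k * c_in))`),
#' biases start at zero.  Given the same seed the parameter vector is
#' reproducible.
#'
#' @param cfg a [unet_config].
#' @param seed initialization seed.
#' @return A `unet_model`: the configuration, the layer descriptor and a
#'   named list of parameter tensors.
#' @export
build_unet <- function(cfg = unet_config(), seed = 1L) {
  layers <- unet_layers(cfg)
  params <- with_seed(seed, {
    p <- list()
    for (r in seq_len(nrow(layers))) {
      l <- layers[r, ]
      k <- kernel_cells[[l$type]]
      kh <- as.integer(sqrt(k))
      sd <- sqrt(2 / (k * l$in_ch))
      p[[l$name]] <- list(
        W = array(rnorm(k * l$in_ch * l$out_ch, sd = sd),
                  c(kh, kh, l$in_ch, l$out_ch)),
        b = numeric(l$out_ch))
    }
    p
  })
  structure(list(version = 1L, config = cfg, layers = layers, params = params),
            class = "unet_model")
}

#' Count trainable parameters
#'
#' @param model a `unet_model` or `unet_ensemble`.
#' @param ... unused.
#' @return Total number of trainable scalar parameters.
#' @export
count_parameters <- function(model, ...) UseMethod("count_parameters")

#' @export
count_parameters.unet_model <- function(model, ...) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), 1))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base %d, %d conv layers, %d parameters\n",
              x$config$depth, x$config$base_channels, nrow(x$layers),
              count_parameters(x)))
  invisible(x)
}

# ---- internal layer math ------------------------------------------------
# Feature blobs are arrays dim c(H, W, B, C).

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

conv3_fwd <- function(x, p) {
  d <- dim(x)
  cout <- dim(p$W)[4]
  y <- conv3_gemm_fwd(x, p$W, p$b, d[1], d[2], d[3], d[4], cout)
  dim(y) <- c(d[1], d[2], d[3], cout)
  y
}

conv3_bwd <- function(x, p, dy, need_dx = TRUE) {
  d <- dim(x)
  cout <- dim(p$W)[4]
  bw <- conv3_gemm_bwd(x, p$W, dy, d[1], d[2], d[3], d[4], cout, need_dx)
  dW <- bw$dW
  dim(dW) <- dim(p$W)
  dx <- NULL
  if (need_dx) {
    dx <- bw$dx
    dim(dx) <- d
  }
  list(dx = dx, dW = dW, db = bw$db)
}

pool_fwd <- function(x) {
  d <- dim(x)
  mp <- maxpool2x2(x, d[1], d[2], d[3], d[4])
  out <- mp$out
  dim(out) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  list(out = out, argmax = mp$argmax, in_dim = d)
}

pool_bwd <- function(cache, dy) {
  dx <- numeric(prod(cache$in_dim))
  dx[cache$argmax] <- dy
  dim(dx) <- cache$in_dim
  dx
}

up_fwd <- function(x, p) {
  d <- dim(x)
  cin <- d[4]; cout <- dim(p$W)[4]
  H <- d[1]; W <- d[2]; B <- d[3]
  xm <- matrix(x, ncol = cin)
  out <- array(0, c(2L * H, 2L * W, B, cout))
  for (di in 0:1) for (dj in 0:1) {
    Wp <- matrix(p$W[di + 1L, dj + 1L, , ], cin, cout)
    out[seq(1L + di, 2L * H, 2L), seq(1L + dj, 2L * W, 2L), , ] <-
      array(xm %*% Wp, c(H, W, B, cout))
  }
  out + rep(p$b, each = 4L * H * W * B)
}

up_bwd <- function(x, p, dy) {
  d <- dim(x)
  cin <- d[4]; cout <- dim(p$W)[4]
  H <- d[1]; W <- d[2]; B <- d[3]
  xm <- matrix(x, ncol = cin)
  dW <- array(0, dim(p$W))
  dxm <- matrix(0, nrow(xm), cin)
  for (di in 0:1) for (dj in 0:1) {
    dyp <- matrix(dy[seq(1L + di, 2L * H, 2L), seq(1L + dj, 2L * W, 2L), , ,
                     drop = FALSE], ncol = cout)
    Wp <- matrix(p$W[di + 1L, dj + 1L, , ], cin, cout)
    dW[di + 1L, dj + 1L, , ] <- crossprod(xm, dyp)
    dxm <- dxm + dyp %*% t(Wp)
  }
  db <- colSums(matrix(dy, ncol = cout))
  dim(dxm) <- d
  list(dx = dxm, dW = dW, db = db)
}

conv1_fwd <- function(x, p) {
  d <- dim(x)
  cout <- dim(p$W)[4]
  xm <- matrix(x, ncol = d[4])
  y <- xm %*% matrix(p$W, d[4], cout)
  y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(d[1], d[2], d[3], cout)
  y
}

conv1_bwd <- function(x, p, dy) {
  d <- dim(x)
  cout <- dim(p$W)[4]
  xm <- matrix(x, ncol = d[4])
  dym <- matrix(dy, ncol = cout)
  dW <- crossprod(xm, dym)
  dim(dW) <- dim(p$W)
  db <- colSums(dym)
  dx <- dym %*% t(matrix(p$W, d[4], cout))
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3], da[4] + db[4]))
}

# Full forward pass.  x: blob dim c(H, W, B, in_channels).  Returns the
# sigmoid probability array dim c(H, W, B) and, when `keep` is TRUE, the
# activation cache needed by nn_backward().
nn_forward <- function(model, x, keep = FALSE) {
  P <- model$params
  depth <- model$config$depth
  d <- dim(x)
  if (d[1] %% 2L^depth != 0L || d[2] %% 2L^depth != 0L)
    stop_input("input height and width must be multiples of ", 2L^depth,
               " for depth ", depth, " (got ", d[1], " x ", d[2], ")")
  cache <- if (keep) new.env(parent = emptyenv()) else NULL
  put <- function(nm, v) if (keep) assign(nm, v, envir = cache)
  skips <- vector("list", depth)
  h <- x
  for (i in seq_len(depth)) {
    put(paste0("e", i, "in1"), h)
    a1 <- relu(conv3_fwd(h, P[[paste0("e", i, "c1")]]))
    put(paste0("e", i, "a1"), a1)
    a2 <- relu(conv3_fwd(a1, P[[paste0("e", i, "c2")]]))
    put(paste0("e", i, "a2"), a2)
    skips[[i]] <- a2
    pl <- pool_fwd(a2)
    put(paste0("e", i, "pool"), pl[c("argmax", "in_dim")])
    h <- pl$out
  }
  put("bin", h)
  b1 <- relu(conv3_fwd(h, P$bc1))
  put("ba1", b1)
  h <- relu(conv3_fwd(b1, P$bc2))
  put("ba2", h)
  for (i in rev(seq_len(depth))) {
    put(paste0("d", i, "uin"), h)
    u <- up_fwd(h, P[[paste0("d", i, "u")]])
    z <- concat_c(u, skips[[i]])
    put(paste0("d", i, "z"), z)
    a1 <- relu(conv3_fwd(z, P[[paste0("d", i, "c1")]]))
    put(paste0("d", i, "a1"), a1)
    h <- relu(conv3_fwd(a1, P[[paste0("d", i, "c2")]]))
    put(paste0("d", i, "a2"), h)
  }
  put("hin", h)
  logits <- conv1_fwd(h, P$head)
  prob <- sigmoid(logits)
  dim(prob) <- d[1:3]
  list(prob = prob, cache = cache)
}

# Backward pass from the gradient w.r.t. the head logits (same shape as the
# probability output).  Returns gradients named like the parameters.
nn_backward <- function(model, cache, dlogit) {
  P <- model$params
  depth <- model$config$depth
  G <- list()
  dim(dlogit) <- c(dim(dlogit), 1L)
  bw <- conv1_bwd(get("hin", cache), P$head, dlogit)
  G$head <- bw[c("dW", "db")]
  dh <- bw$dx
  dskip <- vector("list", depth)
  for (i in seq_len(depth)) {          # decoder stages 1 .. depth (reverse of fwd)
    a2 <- get(paste0("d", i, "a2"), cache)
    a1 <- get(paste0("d", i, "a1"), cache)
    z <- get(paste0("d", i, "z"), cache)
    bw <- conv3_bwd(a1, P[[paste0("d", i, "c2")]], dh * (a2 > 0))
    G[[paste0("d", i, "c2")]] <- bw[c("dW", "db")]
    bw <- conv3_bwd(z, P[[paste0("d", i, "c1")]], bw$dx * (a1 > 0))
    G[[paste0("d", i, "c1")]] <- bw[c("dW", "db")]
    dz <- bw$dx
    c_skip <- dim(get(paste0("e", i, "a2"), cache))[4]
    cu <- dim(dz)[4] - c_skip
    du <- dz[, , , seq_len(cu), drop = FALSE]
    dskip[[i]] <- dz[, , , cu + seq_len(c_skip), drop = FALSE]
    bw <- up_bwd(get(paste0("d", i, "uin"), cache), P[[paste0("d", i, "u")]], du)
    G[[paste0("d", i, "u")]] <- bw[c("dW", "db")]
    dh <- bw$dx
  }
  ba2 <- get("ba2", cache); ba1 <- get("ba1", cache)
  bw <- conv3_bwd(ba1, P$bc2, dh * (ba2 > 0))
  G$bc2 <- bw[c("dW", "db")]
  bw <- conv3_bwd(get("bin", cache), P$bc1, bw$dx * (ba1 > 0))
  G$bc1 <- bw[c("dW", "db")]
  dh <- bw$dx
  for (i in rev(seq_len(depth))) {     # encoder stages depth .. 1
    pl <- get(paste0("e", i, "pool"), cache)
    da2 <- pool_bwd(pl, dh) + dskip[[i]]
    a2 <- get(paste0("e", i, "a2"), cache)
    a1 <- get(paste0("e", i, "a1"), cache)
    bw <- conv3_bwd(a1, P[[paste0("e", i, "c2")]], da2 * (a2 > 0))
    G[[paste0("e", i, "c2")]] <- bw[c("dW", "db")]
    bw <- conv3_bwd(get(paste0("e", i, "in1"), cache),
                    P[[paste0("e", i, "c1")]], bw$dx * (a1 > 0),
                    need_dx = i > 1)   # input-layer gradient is never used
    G[[paste0("e", i, "c1")]] <- bw[c("dW", "db")]
    dh <- bw$dx
  }
  G
}

# Stack a list of H x W x 3 images into a blob dim c(H, W, B, 3).
images_to_blob <- function(images) {
  d <- dim(images[[1]])
  x <- array(unlist(lapply(images, unclass), use.names = FALSE),
             c(d[1], d[2], d[3], length(images)))
  aperm(x, c(1, 2, 4, 3))
}

masks_to_blob <- function(masks) {
  d <- dim(masks[[1]])
  array(unlist(masks, use.names = FALSE), c(d[1], d[2], length(masks)))
}

#' Predict per-pixel crop probabilities
#'
#' Runs the forward pass on one image or a list of equally sized images.
#' Heights and widths must be multiples of `2^depth`; other sizes raise an
#' error naming the required multiple.  The forward pass is deterministic
#' given fixed parameters.
#'
#' @param object a `unet_model`.
#' @param newdata an [image_tensor], a plain `H x W x 3` array, or a list of
#'   them.
#' @param batch_size images per forward batch.
#' @param ... unused.
#' @return An `H x W` probability matrix in `[0, 1]`, or a list of them.
#' @export
predict.unet_model <- function(object, newdata, batch_size = 8L, ...) {
  single <- !is.list(newdata) || inherits(newdata, "image_tensor")
  images <- if (single) list(newdata) else newdata
  out <- vector("list", length(images))
  idx <- seq_along(images)
  for (grp in split(idx, ceiling(idx / batch_size))) {
    x <- images_to_blob(images[grp])
    p <- nn_forward(object, x)$prob
    for (t in seq_along(grp)) out[[grp[t]]] <- p[, , t]
  }
  if (single) out[[1]] else out
}

#' Save or load a model checkpoint
#'
#' Checkpoints store a format version, the architecture configuration and
#' the parameter tensors in a single file.
#'
#' @param model a `unet_model`.
#' @param path file path.
#' @return `load_model()` returns the restored `unet_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "unet_model") || is.null(m$version))
    stop_input("not a unet_model checkpoint: ", path)
  m
}
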