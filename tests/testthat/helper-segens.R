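# Shared fixtures and independent oracles, all built in code.

# Scalar hexcone RGB -> HSV reference, written directly from the standard
# piecewise formulas; kept independent of the package's vectorized path.
ref_rgb2hsv_px <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  v <- mx
  s <- if (mx > 0) d / mx else 0
  h <- if (d == 0) 0
  else if (mx == r) (((g - b) / d) %% 6) / 6
  else if (mx == g) ((b - r) / d + 2) / 6
  else ((r - g) / d + 4) / 6
  c(h %% 1, s, v)
}

rand_rgb_tensor <- function(h, w, seed) {
  set.seed(seed)
  image_tensor(array(runif(h * w * 3), c(h, w, 3)), "rgb")
}

rand_mask <- function(h, w, p = 0.5) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# Dataset of n tiny placeholder items, enough for split bookkeeping tests.
dummy_dataset <- function(n, scene = rep(NA_integer_, n)) {
  img <- image_tensor(array(0.5, c(2, 2, 3)), "rgb")
  msk <- matrix(0L, 2, 2)
  seg_dataset(views = list(rgb = rep(list(img), n)),
              masks = rep(list(msk), n), scene = scene)
}

# Small real scene collection for training tests.
tiny_scenes <- function(n, seed0 = 100, size = 32) {
  spec <- scene_spec(height = size, width = size, n_plants = 2,
                     weed_count = 1, seed = 1)
  lapply(seq_len(n), function(i) {
    s <- spec; s$seed <- seed0 + i
    generate_scene(s)
  })
}

tiny_split_dataset <- function(n = 8, size = 16, seed = 5) {
  spec <- scene_spec(height = size, width = size, n_plants = 1,
                     leaves_per_plant = c(2, 3), weed_count = 0, seed = 1)
  ds <- generate_dataset(spec, n_raw = n, augment_to = n, seed = seed)
  split_dataset(ds, seed = seed)
}

# Direct loop-nest 3x3 same-padding convolution used as the oracle for the
# GEMM-based implementation.
naive_conv3 <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; B <- d[3]; C <- d[4]
  Co <- dim(W)[4]
  out <- array(0, c(H, Wd, B, Co))
  for (co in seq_len(Co)) for (bb in seq_len(B)) for (j in seq_len(Wd))
    for (i in seq_len(H)) {
      s <- b[co]
      for (c in seq_len(C)) for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd)
          s <- s + x[ii, jj, bb, c] * W[di + 2, dj + 2, c, co]
      }
      out[i, j, bb, co] <- s
    }
  out
}
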