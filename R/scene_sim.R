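#' Specification of a synthetic field scene
#'
#' Describes a top-down field scene: crop plants rendered as rosettes of
#' elliptical leaves over a mottled soil background, a few small green weed
#' blobs that are labeled background, a smooth multiplicative brightness
#' gradient emulating natural illumination, and additive pixel noise.  The
#' crop and soil hue intervals (turn-fractions) must be disjoint.
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: 64 x 64 scenes, three plants, green foliage (hue 0.23-0.38) on
#' brown soil (hue 0.05-0.11), a 35% illumination gradient, two weeds and
#' mild sensor noise.
#'
#' @param height,width scene size in pixels.
#' @param n_plants number of crop plants (>= 0).
#' @param leaves_per_plant integer range `c(min, max)` of leaves per plant.
#' @param crop_hue_range,soil_hue_range disjoint hue intervals
#'   (turn-fractions in `[0, 1)`).
#' @param illumination_amplitude strength in `[0, 1)` of the multiplicative
#'   brightness ramp across the scene (0 disables it).
#' @param weed_count number of small green blobs labeled background.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed integer seed making the rendered scene deterministic.
#' @return A `scene_spec` object (a validated list).
#' @export
scene_spec <- function(height = 64, width = 64, n_plants = 3,
                       leaves_per_plant = c(3, 6),
                       crop_hue_range = c(0.23, 0.38),
                       soil_hue_range = c(0.05, 0.11),
                       illumination_amplitude = 0.35,
                       weed_count = 2, noise_sd = 0.02, seed = 1L) {
  if (!is_count(height, 1) || !is_count(width, 1))
    stop_input("`height` and `width` must be positive integers")
  if (!is_count(n_plants, 0)) stop_input("`n_plants` must be a count >= 0")
  if (!is_count(weed_count, 0)) stop_input("`weed_count` must be a count >= 0")
  lpp <- as.integer(leaves_per_plant)
  if (length(lpp) != 2 || any(lpp < 1) || lpp[1] > lpp[2])
    stop_input("`leaves_per_plant` must be an increasing pair of counts")
  chk_range <- function(r, nm) {
    if (length(r) != 2 || any(r < 0) || any(r >= 1) || r[1] >= r[2])
      stop_input("`", nm, "` must be an increasing interval inside [0, 1)")
  }
  chk_range(crop_hue_range, "crop_hue_range")
  chk_range(soil_hue_range, "soil_hue_range")
  if (crop_hue_range[1] < soil_hue_range[2] && soil_hue_range[1] < crop_hue_range[2])
    stop_input("crop and soil hue ranges must be disjoint")
  if (illumination_amplitude < 0 || illumination_amplitude >= 1)
    stop_input("`illumination_amplitude` must lie in [0, 1)")
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_plants = as.integer(n_plants), leaves_per_plant = lpp,
                 crop_hue_range = as.numeric(crop_hue_range),
                 soil_hue_range = as.numeric(soil_hue_range),
                 illumination_amplitude = as.numeric(illumination_amplitude),
                 weed_count = as.integer(weed_count),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "scene_spec")
}

# Rasterize one ellipse onto a logical H x W matrix.  Pixel (i, j) covers
# [j-1, j) x [i-1, i) in (x, y) image coordinates; its center is tested.
ellipse_mask <- function(H, W, cx, cy, a, b, theta) {
  x <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  y <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  dx <- x - cx; dy <- y - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

#' Render a synthetic field scene with its ground-truth mask
#'
#' Deterministic given `spec$seed`: the same spec always renders the same
#' scene bit for bit.  The mask is 1 exactly on crop-leaf pixels; weed blobs
#' are drawn in crop-like greens but labeled 0.  The returned mask carries an
#' `"ellipses"` attribute with the sampled leaf geometry (center, axes,
#' orientation) for inspection.
#'
#' @param spec a [scene_spec].
#' @return A list with elements `image` (RGB [image_tensor]) and `mask`
#'   (integer `H x W` matrix of 0/1).
#' @examples
#' sc <- generate_scene(scene_spec(seed = 7))
#' mean(sc$mask)   # crop-pixel fraction
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width
  if (H < 1 || W < 1) stop_input("zero-area scene")
  S <- min(H, W)
  with_seed(spec$seed, {
    # soil: smoothly mottled hue/saturation/value fields
    mottle <- function(center, amp, sigma = S / 10) {
      f <- gauss_blur(matrix(rnorm(H * W), H, W), sigma)
      f <- f / max(1e-8, stats::sd(f))
      center + amp * f
    }
    hue <- clamp01(mottle(mean(spec$soil_hue_range),
                          diff(spec$soil_hue_range) / 4))
    sat <- clamp01(mottle(runif(1, 0.35, 0.55), 0.08))
    val <- clamp01(mottle(runif(1, 0.45, 0.65), 0.10))
    mask <- matrix(FALSE, H, W)
    ellipses <- NULL

    paint_blob <- function(cx, cy, a, b, theta, hue_rng, s_rng, v_rng) {
      m <- ellipse_mask(H, W, cx, cy, a, b, theta)
      hue[m] <<- runif(1, hue_rng[1], hue_rng[2])
      sat[m] <<- runif(1, s_rng[1], s_rng[2])
      val[m] <<- runif(1, v_rng[1], v_rng[2])
      m
    }

    if (spec$n_plants > 0) {
      for (p in seq_len(spec$n_plants)) {
        cx <- runif(1, 0.15 * W, 0.85 * W)
        cy <- runif(1, 0.15 * H, 0.85 * H)
        n_leaves <- sample(spec$leaves_per_plant[1]:spec$leaves_per_plant[2], 1)
        for (l in seq_len(n_leaves)) {
          theta <- runif(1, 0, pi)
          a <- runif(1, 0.06, 0.16) * S
          b <- runif(1, 0.025, 0.06) * S
          # leaf grows outward from the plant center along its own axis
          lx <- cx + cos(theta) * a * 0.7
          ly <- cy + sin(theta) * a * 0.7
          m <- paint_blob(lx, ly, a, b, theta, spec$crop_hue_range,
                          c(0.55, 0.9), c(0.45, 0.85))
          mask <- mask | m
          ellipses <- rbind(ellipses, c(cx = lx, cy = ly, a = a, b = b,
                                        theta = theta))
        }
      }
    }
    if (spec$weed_count > 0) {
      for (w in seq_len(spec$weed_count)) {
        cx <- runif(1, 0.05 * W, 0.95 * W)
        cy <- runif(1, 0.05 * H, 0.95 * H)
        r1 <- runif(1, 0.015, 0.04) * S
        r2 <- runif(1, 0.015, 0.04) * S
        m <- ellipse_mask(H, W, cx, cy, r1, r2, runif(1, 0, pi))
        m <- m & !mask            # weeds never overwrite crop pixels
        hue[m] <- runif(1, spec$crop_hue_range[1], spec$crop_hue_range[2])
        sat[m] <- runif(1, 0.35, 0.6)
        val[m] <- runif(1, 0.4, 0.7)
      }
    }

    hsv <- image_tensor(array(c(clamp01(hue), clamp01(sat), clamp01(val)),
                              c(H, W, 3)), "hsv")
    rgb <- unclass(hsv_to_rgb(hsv))

    if (spec$illumination_amplitude > 0) {
      phi <- runif(1, 0, 2 * pi)
      x <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) / W
      y <- matrix(rep(seq_len(H) - 0.5, times = W), H, W) / H
      ramp <- (x * cos(phi) + y * sin(phi) + 1) / 2   # in [0, 1]
      ramp <- (ramp - min(ramp)) / max(1e-8, diff(range(ramp)))
      factor <- 1 - spec$illumination_amplitude * ramp
      rgb <- rgb * as.vector(factor)                  # scales V, keeps H and S
    }
    if (spec$noise_sd > 0)
      rgb <- rgb + rnorm(length(rgb), sd = spec$noise_sd)

    out_mask <- matrix(as.integer(mask), H, W)
    attr(out_mask, "ellipses") <- ellipses
    list(image = image_tensor(clamp01(rgb), "rgb"), mask = out_mask)
  })
}

#' Augmentation parameters for a paired image/mask transform
#'
#' Geometric components (flips, quarter turns, continuous rotation, zoom and
#' translation) are applied identically to image and mask; the mask is
#' resampled nearest-neighbor so it stays binary.  Pixel components
#' (Gaussian blur, salt-and-pepper noise) touch the image only.  The default
#' is the identity.
#'
#' @param flip_h,flip_v horizontal / vertical mirror.
#' @param rot90 number of exact 90-degree clockwise rotations (0-3).
#' @param angle additional continuous rotation in degrees.
#' @param zoom isotropic scale factor.
#' @param tx,ty translation as a fraction of width / height.
#' @param blur_sigma Gaussian blur standard deviation in pixels (image only).
#' @param sp_density salt-and-pepper corruption density in `[0, 1]`
#'   (image only).
#' @return An `augment_params` list.
#' @export
augment_params <- function(flip_h = FALSE, flip_v = FALSE, rot90 = 0L,
                           angle = 0, zoom = 1, tx = 0, ty = 0,
                           blur_sigma = 0, sp_density = 0) {
  if (!rot90 %in% 0:3) stop_input("`rot90` must be 0, 1, 2 or 3")
  if (zoom <= 0) stop_input("`zoom` must be positive")
  if (sp_density < 0 || sp_density > 1) stop_input("`sp_density` must be in [0, 1]")
  structure(list(flip_h = isTRUE(flip_h), flip_v = isTRUE(flip_v),
                 rot90 = as.integer(rot90), angle = as.numeric(angle),
                 zoom = as.numeric(zoom), tx = as.numeric(tx),
                 ty = as.numeric(ty), blur_sigma = as.numeric(blur_sigma),
                 sp_density = as.numeric(sp_density)),
            class = "augment_params")
}

# Draw mild random augmentation parameters: both flips at 50%, rotation
# within +/-30 degrees, zoom 0.9-1.1, translation within +/-10%, blur
# sigma up to 1 px, salt-and-pepper density 0.01.
random_augment_params <- function() {
  augment_params(flip_h = runif(1) < 0.5, flip_v = runif(1) < 0.5,
                 rot90 = sample(0:3, 1), angle = runif(1, -30, 30),
                 zoom = runif(1, 0.9, 1.1), tx = runif(1, -0.1, 0.1),
                 ty = runif(1, -0.1, 0.1), blur_sigma = runif(1, 0, 1),
                 sp_density = 0.01)
}

rot90_cw <- function(m) {
  # (i, j) -> (j, H - 1 - i) in 0-based indices: transpose, reverse columns
  t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
}

apply_channelwise <- function(img, f) {
  out <- NULL
  for (c in 1:3) out <- c(out, list(f(img[, , c])))
  array(unlist(out), c(dim(out[[1]]), 3))
}

# Inverse-mapped affine resampling around the canvas center.  `interp` is
# "bilinear" (image) or "nearest" (mask); out-of-canvas samples are 0.
affine_resample <- function(m, angle, zoom, tx, ty, interp) {
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  cx <- W / 2; cy <- H / 2
  xo <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cx - tx * W
  yo <- matrix(rep(seq_len(H) - 0.5, times = W), H, W) - cy - ty * H
  xs <- (cos(th) * xo + sin(th) * yo) / zoom + cx
  ys <- (-sin(th) * xo + cos(th) * yo) / zoom + cy
  if (interp == "nearest") {
    j <- floor(xs) + 1; i <- floor(ys) + 1
    ok <- i >= 1 & i <= H & j >= 1 & j <= W
    out <- matrix(0, H, W)
    out[ok] <- m[cbind(i[ok], j[ok])]
    out
  } else {
    x0 <- floor(xs - 0.5); y0 <- floor(ys - 0.5)
    fx <- (xs - 0.5) - x0; fy <- (ys - 0.5) - y0
    pick <- function(ii, jj) {
      ok <- ii >= 0 & ii <= H - 1 & jj >= 0 & jj <= W - 1
      out <- matrix(0, H, W)
      out[ok] <- m[cbind(ii[ok] + 1, jj[ok] + 1)]
      out
    }
    pick(y0, x0) * (1 - fx) * (1 - fy) + pick(y0, x0 + 1) * fx * (1 - fy) +
      pick(y0 + 1, x0) * (1 - fx) * fy + pick(y0 + 1, x0 + 1) * fx * fy
  }
}

#' Apply a synchronized augmentation to an image/mask pair
#'
#' Flips and quarter-turn rotations are exact index permutations applied to
#' both members of the pair, so they commute exactly with any mask logic.
#' Continuous rotation/zoom/translation use inverse mapping with bilinear
#' resampling for the image and nearest-neighbor for the mask (regions
#' mapped from outside the canvas become background).  Blur and
#' salt-and-pepper noise perturb the image only.
#'
#' @param img an RGB [image_tensor].
#' @param mask an aligned integer 0/1 matrix of the same height and width.
#' @param params an [augment_params].
#' @param seed optional seed for the stochastic pixel noise.
#' @return A list with the transformed `image` and `mask`.
#' @export
augment_pair <- function(img, mask, params = augment_params(), seed = NULL) {
  stopifnot(inherits(params, "augment_params"))
  d <- dim(img)
  if (d[1] != nrow(mask) || d[2] != ncol(mask))
    stop_input("image and mask dimensions differ")
  if (d[1] < 1 || d[2] < 1) stop_input("empty canvas")
  sp <- image_space(img)
  x <- unclass(img)
  m <- mask
  if (params$flip_h) {           # mirror columns
    x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  }
  if (params$flip_v) {           # mirror rows
    x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  if (params$rot90 > 0) {
    for (k in seq_len(params$rot90)) {
      x <- apply_channelwise(image_tensor(x, sp), rot90_cw)
      m <- rot90_cw(m)
    }
  }
  if (params$angle != 0 || params$zoom != 1 || params$tx != 0 || params$ty != 0) {
    x <- apply_channelwise(image_tensor(clamp01(x), sp), function(ch)
      affine_resample(ch, params$angle, params$zoom, params$tx, params$ty,
                      "bilinear"))
    m <- affine_resample(m, params$angle, params$zoom, params$tx, params$ty,
                         "nearest")
  }
  if (params$blur_sigma > 0)
    x <- apply_channelwise(image_tensor(clamp01(x), sp), function(ch)
      gauss_blur(ch, params$blur_sigma))
  if (params$sp_density > 0) {
    x <- with_seed(seed, {
      n <- nrow(m) * ncol(m)
      hit <- sample.int(n, size = round(params$sp_density * n))
      val <- as.numeric(runif(length(hit)) < 0.5)
      for (c in 1:3) {
        plane <- x[, , c]
        plane[hit] <- val
        x[, , c] <- plane
      }
      x
    })
  }
  list(image = image_tensor(clamp01(x), sp),
       mask = matrix(as.integer(m != 0), nrow(m), ncol(m)))
}

#' Aligned multi-view segmentation dataset
#'
#' A `seg_dataset` holds index-aligned collections: one image list per color
#' space view (`rgb`, `hsv`), the ground-truth `masks`, a `split` tag per
#' item (`"train"`, `"val"`, `"test"`, or `NA` before splitting) and the
#' originating base-scene index of each item.
#'
#' @param views named list of image lists (all the same length).
#' @param masks list of 0/1 matrices aligned with the views.
#' @param split character vector of split tags (or `NA`).
#' @param scene integer vector of base-scene ids.
#' @return A `seg_dataset`.
#' @export
seg_dataset <- function(views, masks, split = rep(NA_character_, length(masks)),
                        scene = rep(NA_integer_, length(masks))) {
  n <- length(masks)
  if (!length(views) || !all(vapply(views, length, 1L) == n))
    stop_input("all views must have the same length as `masks`")
  d0 <- dim(masks[[1]])
  for (v in views) for (im in v)
    if (!all(dim(im)[1:2] == d0)) stop_input("view/mask dimensions differ")
  structure(list(views = views, masks = masks,
                 split = as.character(split), scene = as.integer(scene)),
            class = "seg_dataset")
}

#' @export
print.seg_dataset <- function(x, ...) {
  d <- dim(x$masks[[1]])
  tab <- table(factor(x$split, levels = c("train", "val", "test")), useNA = "ifany")
  cat(sprintf("<seg_dataset> %d items, %d x %d, views: %s\n",
              length(x$masks), d[1], d[2], paste(names(x$views), collapse = ", ")))
  cat("  split:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
length.seg_dataset <- function(x) length(x$masks)

#' Expand a dataset with randomized augmentations and derive the HSV view
#'
#' Keeps the existing items, appends randomized augmentations of them until
#' the dataset holds `augment_to` items, and (re)derives the HSV view from
#' every (augmented) RGB image so both views depict identical geometry and
#' share the mask.  Split tags are reset.
#'
#' @param ds a [seg_dataset] with an `rgb` view.
#' @param augment_to total number of items (>= current size).
#' @param seed seed for the augmentation draws.
#' @return A [seg_dataset] with views `rgb` and `hsv`, unsplit.
#' @export
augment_dataset <- function(ds, augment_to, seed = 1L) {
  stopifnot(inherits(ds, "seg_dataset"))
  n0 <- length(ds)
  if (!is_count(augment_to, n0))
    stop_input("`augment_to` must be >= the current dataset size (", n0, ")")
  rgb <- ds$views$rgb
  if (is.null(rgb)) stop_input("dataset has no rgb view")
  msk <- ds$masks
  scene_id <- if (all(is.na(ds$scene))) seq_len(n0) else ds$scene
  with_seed(seed, {
    n_extra <- augment_to - n0
    if (n_extra > 0) {
      base_idx <- sample(rep_len(seq_len(n0), n_extra))
      for (t in seq_len(n_extra)) {
        b <- base_idx[t]
        aug <- augment_pair(rgb[[b]], msk[[b]], random_augment_params(),
                            seed = sample.int(.Machine$integer.max - 1L, 1))
        rgb <- c(rgb, list(aug$image))
        msk <- c(msk, list(aug$mask))
        scene_id <- c(scene_id, scene_id[b])
      }
    }
    hsv <- lapply(rgb, rgb_to_hsv)
    seg_dataset(views = list(rgb = rgb, hsv = hsv), masks = msk,
                scene = scene_id)
  })
}

#' Generate an augmented two-view dataset of synthetic scenes
#'
#' Renders `n_raw` base scenes from `spec` (with per-scene derived seeds),
#' keeps them as the first items, and fills up to `augment_to` items with
#' randomized augmentations of the base scenes via [augment_dataset()].
#'
#' @param spec a [scene_spec].
#' @param n_raw number of base scenes (>= 1).
#' @param augment_to total number of items (>= `n_raw`).
#' @param seed master seed for scene rendering and augmentation draws.
#' @return A [seg_dataset] with views `rgb` and `hsv`, unsplit.
#' @export
generate_dataset <- function(spec, n_raw, augment_to = n_raw, seed = 1L) {
  if (!is_count(n_raw, 1) || !is_count(augment_to, n_raw))
    stop_input("need augment_to >= n_raw >= 1")
  base <- with_seed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max - 1L, n_raw)
    scenes <- lapply(seq_len(n_raw), function(i) {
      s <- spec; s$seed <- scene_seeds[i]
      generate_scene(s)
    })
    rgb <- lapply(scenes, `[[`, "image")
    msk <- lapply(scenes, function(s) {
      m <- s$mask; attributes(m) <- list(dim = dim(m)); m
    })
    seg_dataset(views = list(rgb = rgb), masks = msk, scene = seq_len(n_raw))
  })
  augment_dataset(base, augment_to, seed = derive_seed(seed, 1L))
}

#' Assign train/validation/test split tags
#'
#' Splits the items of a dataset at the given ratios (default 7:2:1).
#' Subset sizes are `floor(N * r / sum(r))` with the remainder assigned to
#' the training set; the assignment is a seeded permutation.  With
#' `by = "scene"` whole base scenes (and all their augmented copies) are
#' kept inside one split, avoiding near-duplicate leakage.
#'
#' @param ds a [seg_dataset].
#' @param ratios three positive numbers (train, val, test).
#' @param seed permutation seed.
#' @param by `"item"` (default) or `"scene"`.
#' @return The dataset with `split` tags filled in.
#' @export
split_dataset <- function(ds, ratios = c(7, 2, 1), seed = 1L,
                          by = c("item", "scene")) {
  stopifnot(inherits(ds, "seg_dataset"))
  by <- match.arg(by)
  n <- length(ds)
  if (n < 1) stop_input("empty dataset")
  if (length(ratios) != 3 || any(ratios <= 0)) stop_input("ratios must be 3 positive numbers")
  sizes <- floor(n * ratios / sum(ratios))
  sizes[1] <- sizes[1] + (n - sum(sizes))     # remainder -> train
  tags <- rep(c("train", "val", "test"), times = sizes)
  with_seed(seed, {
    if (by == "item") {
      ds$split[sample.int(n)] <- tags
    } else {
      if (all(is.na(ds$scene))) stop_input("dataset has no scene ids")
      split <- rep(NA_character_, n)
      # fill the smallest quotas first so every split receives whole scenes;
      # scene-level sizes are approximate by construction
      deficit <- c(test = sizes[3], val = sizes[2], train = n)
      for (sc in sample(unique(ds$scene))) {
        items <- which(ds$scene == sc)
        tgt <- if (deficit["test"] > 0) "test"
               else if (deficit["val"] > 0) "val" else "train"
        split[items] <- tgt
        deficit[tgt] <- deficit[tgt] - length(items)
      }
      ds$split <- split
    }
  })
  ds
}

# Extract the images of one view restricted to a split tag.
dataset_subset <- function(ds, view, split) {
  idx <- which(ds$split == split)
  list(images = ds$views[[view]][idx], masks = ds$masks[idx], index = idx)
}
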