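#' Two-view ensemble benchmark on synthetic field scenes
#'
#' Runs the full pipeline once per seed: render `n_raw` base scenes,
#' augment to `augment_to` items, split 7:2:1, train the RGB-view and
#' HSV-view members, then score the test split three ways — each member
#' alone and the weighted fusion of both.  This is the package's standing
#' experiment for the claim that the two color spaces carry complementary
#' information which pixel-wise fusion can exploit.
#'
#' @param spec a [scene_spec] describing the scenes (the default includes
#'   the illumination gradient that makes the two views disagree).
#' @param n_raw,augment_to dataset sizes (defaults 30 raw, 400 augmented).
#' @param seeds one seed per replicate run.
#' @param epochs training epochs per member.
#' @param member member architecture.
#' @param lr,batch_size optimization settings.
#' @param ratios train/val/test ratios.
#' @param verbose print per-run progress.
#' @return A data frame with one row per seed: mean test IoU of the RGB
#'   member, the HSV member and the fused ensemble, plus fused test pixel
#'   accuracy.
#' @export
benchmark_ensemble <- function(spec = scene_spec(), n_raw = 30,
                               augment_to = 400, seeds = 1:3, epochs = 8,
                               member = unet_config(depth = 3, base_channels = 8),
                               lr = 1e-3, batch_size = 8L,
                               ratios = c(7, 2, 1), verbose = FALSE) {
  rows <- lapply(seeds, function(seed) {
    ds <- generate_dataset(spec, n_raw = n_raw, augment_to = augment_to,
                           seed = seed)
    ds <- split_dataset(ds, ratios = ratios, seed = derive_seed(seed, 2L))
    cfg <- ensemble_config(k = 2, epochs = epochs, member = member, lr = lr,
                           batch_size = batch_size, seed = seed)
    ens <- train_ensemble(ds, cfg, verbose = verbose)
    te_rgb <- dataset_subset(ds, "rgb", "test")
    te_hsv <- dataset_subset(ds, "hsv", "test")
    member_maps <- list(rgb = predict(ens$members[[1]], te_rgb$images),
                        hsv = predict(ens$members[[2]], te_hsv$images))
    fused <- lapply(seq_along(te_rgb$masks), function(t)
      fuse_predictions(list(member_maps$rgb[[t]], member_maps$hsv[[t]]),
                       ens$weights))
    score <- function(maps) mean(mapply(function(p, m)
      iou(classify(p, cfg$threshold), m), maps, te_rgb$masks))
    acc <- mean(mapply(function(p, m)
      pixel_accuracy(classify(p, cfg$threshold), m), fused, te_rgb$masks))
    if (verbose)
      message(sprintf("seed %d: rgb %.4f hsv %.4f fused %.4f",
                      seed, score(member_maps$rgb), score(member_maps$hsv),
                      score(fused)))
    data.frame(seed = seed, rgb_iou = score(member_maps$rgb),
               hsv_iou = score(member_maps$hsv), fused_iou = score(fused),
               fused_accuracy = acc)
  })
  do.call(rbind, rows)
}
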