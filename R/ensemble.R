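#' Construct an ensemble weight vector
#'
#' Member weights are non-negative and sum to 1.  Three schemes are
#' supported: `"constant"` gives every member `1/k`; `"abundance"` uses the
#' supplied data-share fractions directly (a member receiving 10% of the
#' data gets weight 0.1); `"random"` draws seeded uniform weights and
#' normalizes them to sum 1.
#'
#' @param scheme `"constant"`, `"abundance"` or `"random"`.
#' @param k number of ensemble members.
#' @param abundances for the abundance scheme, `k` fractions summing to 1.
#' @param seed seed for the random scheme.
#' @return A `weight_vector` (numeric of length `k`).
#' @examples
#' make_weights("constant", 2)            # 0.5 0.5
#' make_weights("abundance", 2, c(0.1, 0.9))
#' @export
make_weights <- function(scheme = c("constant", "abundance", "random"), k,
                         abundances = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (!is_count(k, 1)) stop_input("`k` must be a positive integer")
  w <- switch(scheme,
    constant = rep(1 / k, k),
    abundance = {
      if (is.null(abundances) || length(abundances) != k)
        stop_input("abundance scheme needs `k` fractions")
      if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-8)
        stop_input("abundances must be non-negative and sum to 1")
      as.numeric(abundances)
    },
    random = with_seed(seed, {
      u <- runif(k)
      u / sum(u)
    }))
  as_weight_vector(w)
}

as_weight_vector <- function(w) {
  validate_weights(w)
  structure(as.numeric(w), class = "weight_vector")
}

validate_weights <- function(w) {
  if (!is.numeric(w) || length(w) < 1 || any(w < 0))
    stop_input("weights must be non-negative numbers")
  if (abs(sum(w) - 1) > 1e-9)
    stop_input("weights must sum to 1 (got ", format(sum(w), digits = 12), ")")
  invisible(w)
}

#' Weighted ensemble loss
#'
#' The weighted sum of member losses, `sum(w_i * L_i)`; with constant
#' weights `[0.5, 0.5]` this is the arithmetic mean of two member losses.
#'
#' @param member_losses numeric vector of `k` member losses.
#' @param weights a weight vector of matching length (non-negative, summing
#'   to 1).
#' @return A single number.
#' @export
ensemble_loss <- function(member_losses, weights) {
  validate_weights(weights)
  if (length(member_losses) != length(weights))
    stop_input("lengths of losses and weights differ")
  sum(as.numeric(weights) * member_losses)
}

#' Ensemble training configuration
#'
#' Bundles the ensemble hyper-parameters: the member count `k`, the member
#' weight vector, the epoch count, the fusion threshold, the member
#' architecture and the optimization settings.  The defaults follow the
#' two-view study configuration: `k = 2` members trained on the RGB and HSV
#' views with constant weights `[0.5, 0.5]`, 50 epochs and threshold 0.5.
#'
#' @param k member count (>= 1).
#' @param weights a weight vector of length `k`.
#' @param epochs training epochs `n`.
#' @param threshold fusion threshold `alpha` in (0, 1).
#' @param member a [unet_config] shared by all members.
#' @param views names of the dataset views feeding the members (length `k`).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed training seed.
#' @param bootstrap if `TRUE`, each member additionally sees a bootstrap
#'   subsample of its view rather than every item.
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(k = 2, weights = make_weights("constant", k),
                            epochs = 50, threshold = 0.5,
                            member = unet_config(),
                            views = if (k == 2) c("rgb", "hsv") else
                              rep("rgb", k),
                            lr = 1e-3, batch_size = 8L, seed = 1L,
                            bootstrap = FALSE) {
  if (!is_count(k, 1)) stop_input("`k` must be a positive integer")
  validate_weights(weights)
  if (length(weights) != k) stop_input("`weights` must have length k")
  if (!is_count(epochs, 1)) stop_input("`epochs` must be a positive integer")
  if (threshold <= 0 || threshold >= 1) stop_input("`threshold` must lie in (0, 1)")
  if (length(views) != k) stop_input("`views` must name one dataset view per member")
  structure(list(k = as.integer(k), weights = as_weight_vector(weights),
                 epochs = as.integer(epochs), threshold = as.numeric(threshold),
                 member = member, views = as.character(views),
                 lr = as.numeric(lr), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), bootstrap = isTRUE(bootstrap)),
            class = "ensemble_config")
}

#' Train a bagging ensemble of UNets over color-space views
#'
#' Trains `k` independent members, member `i` seeing only the dataset view
#' `cfg$views[i]` (its bagging subset): no member ever reads another's
#' parameters, so members could be trained in parallel.  Every member is
#' initialized and shuffled from the same seed, which makes the recorded
#' history invariant to jointly permuting members and weights.  The
#' per-epoch weighted loss is `LO_j = sum_i w_i * LO_ji`; member accuracies
#' `AC_ji` are summed into `AC_j`, and both running totals are averaged
#' over the `n` epochs at the end.
#'
#' @param ds a [seg_dataset] with split tags (members train on the
#'   `"train"` items and are monitored on `"val"`).
#' @param cfg an [ensemble_config]; `cfg$views` must match `k` and name
#'   existing views of `ds`.
#' @param verbose print per-epoch progress.
#' @return A `unet_ensemble`: member models, weights, the fusion threshold
#'   and a `training_history`.
#' @export
train_ensemble <- function(ds, cfg = ensemble_config(), verbose = FALSE) {
  stopifnot(inherits(ds, "seg_dataset"), inherits(cfg, "ensemble_config"))
  missing <- setdiff(cfg$views, names(ds$views))
  if (length(missing))
    stop_input("config asks for ", cfg$k, " member view(s) but dataset lacks: ",
               paste(missing, collapse = ", "))
  if (!any(ds$split == "train", na.rm = TRUE))
    stop_input("dataset has no training split; call split_dataset() first")
  members <- vector("list", cfg$k)
  names(members) <- make.unique(cfg$views)
  n_ep <- cfg$epochs
  LO <- AC <- VL <- matrix(NA_real_, n_ep, cfg$k)
  for (i in seq_len(cfg$k)) {
    tr <- dataset_subset(ds, cfg$views[i], "train")
    va <- dataset_subset(ds, cfg$views[i], "val")
    if (cfg$bootstrap) {
      pick <- with_seed(derive_seed(cfg$seed, 100L + i),
                        sample(length(tr$images), replace = TRUE))
      tr$images <- tr$images[pick]
      tr$masks <- tr$masks[pick]
    }
    fit <- train_unet(tr$images, tr$masks, cfg$member, epochs = n_ep,
                      lr = cfg$lr, batch_size = cfg$batch_size,
                      seed = cfg$seed, val_images = va$images,
                      val_masks = va$masks, threshold = cfg$threshold,
                      verbose = verbose)
    members[[i]] <- fit$model
    LO[, i] <- fit$history$loss
    AC[, i] <- fit$history$accuracy
    VL[, i] <- fit$history$val_loss
  }
  w <- as.numeric(cfg$weights)
  history <- structure(list(
    member_loss = LO, member_accuracy = AC, member_val_loss = VL,
    loss = drop(LO %*% w), accuracy = rowSums(AC),
    val_loss = drop(VL %*% w),
    avg_loss = sum(LO %*% w) / n_ep,
    avg_accuracy = sum(rowSums(AC)) / n_ep,
    mean_member_accuracy = mean(AC[n_ep, ])), class = "training_history")
  structure(list(version = 1L, members = members, weights = cfg$weights,
                 threshold = cfg$threshold, views = cfg$views, config = cfg,
                 history = history),
            class = "unet_ensemble")
}

#' @export
print.unet_ensemble <- function(x, ...) {
  cat(sprintf("<unet_ensemble> k = %d (views: %s), weights [%s], threshold %.2f\n",
              length(x$members), paste(x$views, collapse = ", "),
              paste(format(as.numeric(x$weights)), collapse = ", "),
              x$threshold))
  invisible(x)
}

#' @export
count_parameters.unet_ensemble <- function(model, ...) {
  sum(vapply(model$members, count_parameters, 1))
}

#' Fuse member probability maps pixel-wise
#'
#' Weighted per-pixel sum `sum_i w_i * p_i` of the member maps.  Because
#' the weights sum to 1 the fusion is a convex combination: every fused
#' pixel lies between the member minimum and maximum, and in particular
#' stays in `[0, 1]`.
#'
#' @param maps list of `k` probability matrices of identical shape.
#' @param weights a weight vector of length `k`.
#' @return The fused probability matrix.
#' @export
fuse_predictions <- function(maps, weights) {
  validate_weights(weights)
  if (length(maps) != length(weights))
    stop_input("number of maps and weights differ")
  d <- dim(maps[[1]])
  for (m in maps) if (!all(dim(m) == d)) stop_input("probability map shapes differ")
  out <- maps[[1]] * weights[1]
  for (i in seq_along(maps)[-1]) out <- out + maps[[i]] * weights[i]
  out
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is classified as crop (1) when its crop probability is at least
#' `alpha`, background (0) otherwise; a tie at exactly `alpha` goes to
#' crop.
#'
#' @param map probability matrix/array.
#' @param alpha threshold in (0, 1).
#' @return An integer 0/1 array of the same shape.
#' @export
classify <- function(map, alpha = 0.5) {
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must lie in (0, 1)")
  out <- array(as.integer(map >= alpha), dim(map))
  out
}

#' Predict with a trained ensemble
#'
#' Runs every member on its own color-space view of the input, fuses the
#' probability maps with the ensemble weights and (optionally) thresholds
#' the result.
#'
#' @param object a `unet_ensemble`.
#' @param newdata a named list of per-view inputs (`newdata$rgb`,
#'   `newdata$hsv`, ...), each either one image or a list of images.  An
#'   RGB-only input may be given directly; missing HSV views are derived
#'   from RGB on the fly.
#' @param type `"prob"` for fused probability maps, `"mask"` for
#'   thresholded 0/1 masks, `"member"` for the per-member probability maps.
#' @param alpha threshold (defaults to the ensemble's).
#' @param ... unused.
#' @return A matrix (or list of matrices) of fused probabilities or labels.
#' @export
predict.unet_ensemble <- function(object, newdata,
                                  type = c("prob", "mask", "member"),
                                  alpha = object$threshold, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "image_tensor") ||
      (is.array(newdata) && length(dim(newdata)) == 3))
    newdata <- list(rgb = newdata)
  single <- !is.list(newdata[[1]]) || inherits(newdata[[1]], "image_tensor")
  views <- lapply(newdata, function(v) if (single) list(v) else v)
  if (!("hsv" %in% names(views)) && any(object$views == "hsv") &&
      "rgb" %in% names(views))
    views$hsv <- lapply(views$rgb, function(im)
      rgb_to_hsv(if (inherits(im, "image_tensor")) im else image_tensor(im, "rgb")))
  missing <- setdiff(object$views, names(views))
  if (length(missing))
    stop_input("input lacks view(s): ", paste(missing, collapse = ", "))
  member_maps <- lapply(seq_along(object$members), function(i)
    predict(object$members[[i]], views[[object$views[i]]]))
  n <- length(member_maps[[1]])
  fused <- lapply(seq_len(n), function(t)
    fuse_predictions(lapply(member_maps, `[[`, t), object$weights))
  out <- switch(type,
    prob = fused,
    mask = lapply(fused, classify, alpha = alpha),
    member = member_maps)
  if (single && type != "member") out[[1]] else out
}

#' Save or load an ensemble checkpoint directory
#'
#' Members are written as individual checkpoints next to a JSON manifest
#' listing the format version, views, weights and member files.
#'
#' @param ensemble a `unet_ensemble`.
#' @param dir checkpoint directory (created if absent).
#' @return `load_ensemble()` returns the restored `unet_ensemble`.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "unet_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("member_%02d_%s.rds", seq_along(ensemble$members),
                   ensemble$views)
  for (i in seq_along(ensemble$members))
    save_model(ensemble$members[[i]], file.path(dir, files[i]))
  manifest <- list(version = 1L, k = length(ensemble$members),
                   views = ensemble$views,
                   weights = as.numeric(ensemble$weights),
                   threshold = ensemble$threshold, members = files)
  jsonlite::write_json(manifest, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(ensemble$history, file.path(dir, "history.rds"))
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  mf_path <- file.path(dir, "ensemble.json")
  if (!file.exists(mf_path)) stop_input("no ensemble manifest at ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  members <- lapply(file.path(dir, mf$members), load_model)
  names(members) <- make.unique(mf$views)
  hist_path <- file.path(dir, "history.rds")
  structure(list(version = mf$version, members = members,
                 weights = as_weight_vector(mf$weights),
                 threshold = mf$threshold, views = mf$views, config = NULL,
                 history = if (file.exists(hist_path)) readRDS(hist_path)),
            class = "unet_ensemble")
}
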