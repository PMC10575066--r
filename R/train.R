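# Single-member training: minibatch Adam on mean binary cross-entropy.

adam_init <- function(params) {
  lapply(params, function(p) list(mW = array(0, dim(p$W)), vW = array(0, dim(p$W)),
                                  mb = numeric(length(p$b)), vb = numeric(length(p$b))))
}

adam_step <- function(params, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    params[[nm]]$W <- params[[nm]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    params[[nm]]$b <- params[[nm]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# Forward a set of images in batches and return probability maps plus the
# mean BCE loss and pixel accuracy against the given masks.
eval_on_set <- function(model, images, masks, batch_size, threshold = 0.5) {
  n <- length(images)
  loss <- 0; acc <- 0
  idx <- seq_len(n)
  for (grp in split(idx, ceiling(idx / batch_size))) {
    x <- images_to_blob(images[grp])
    y <- masks_to_blob(masks[grp])
    p <- nn_forward(model, x)$prob
    loss <- loss + bce_loss(p, y) * length(grp)
    acc <- acc + pixel_accuracy(classify(p, threshold), y) * length(grp)
  }
  list(loss = loss / n, accuracy = acc / n)
}

#' Train a single UNet on an image/mask collection
#'
#' Minimizes mean binary cross-entropy with minibatch Adam.  Shuffling,
#' initialization and therefore the whole run are reproducible given
#' `seed`.  Per-epoch training loss is the weighted mean of batch losses;
#' accuracy and validation loss are computed on the validation collection
#' at the end of each epoch (falling back to the training collection when
#' no validation data is given).
#'
#' @param images list of `H x W x 3` unit-range images (one color-space view).
#' @param masks list of aligned 0/1 masks.
#' @param cfg a [unet_config].
#' @param epochs number of passes over the data.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed seed for initialization and shuffling.
#' @param val_images,val_masks optional validation collection.
#' @param threshold probability threshold used for the accuracy bookkeeping.
#' @param model optional pre-built `unet_model` to continue training.
#' @param verbose print per-epoch progress.
#' @return A `unet_fit`: list with the trained `model` and a per-epoch
#'   `history` data frame (`loss`, `accuracy`, `val_loss`).
#' @export
train_unet <- function(images, masks, cfg = unet_config(), epochs = 50,
                       lr = 1e-3, batch_size = 8L, seed = 1L,
                       val_images = NULL, val_masks = NULL, threshold = 0.5,
                       model = NULL, verbose = FALSE) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  if (is.null(model)) model <- build_unet(cfg, seed = seed)
  n <- length(images)
  state <- adam_init(model$params)
  t_step <- 0L
  hist <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                     accuracy = NA_real_, val_loss = NA_real_)
  has_val <- !is.null(val_images) && length(val_images) > 0
  with_seed(derive_seed(seed, 17L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (grp in split(ord, ceiling(seq_along(ord) / batch_size))) {
        x <- images_to_blob(images[grp])
        y <- masks_to_blob(masks[grp])
        fw <- nn_forward(model, x, keep = TRUE)
        ep_loss <- ep_loss + bce_loss(fw$prob, y) * length(grp)
        dlogit <- (fw$prob - y) / length(fw$prob)
        grads <- nn_backward(model, fw$cache, dlogit)
        t_step <- t_step + 1L
        upd <- adam_step(model$params, grads, state, t_step, lr)
        model$params <- upd$params
        state <- upd$state
      }
      hist$loss[ep] <- ep_loss / n
      ev <- if (has_val)
        eval_on_set(model, val_images, val_masks, batch_size, threshold)
      else eval_on_set(model, images, masks, batch_size, threshold)
      hist$accuracy[ep] <- ev$accuracy
      hist$val_loss[ep] <- ev$loss
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.4f  val_loss %.4f",
                        ep, hist$loss[ep], hist$accuracy[ep], hist$val_loss[ep]))
    }
  })
  structure(list(model = model, history = hist), class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<unet_fit> %d epochs  final loss %.4f  accuracy %.4f\n",
              nrow(x$history), last$loss, last$accuracy))
  invisible(x)
}
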