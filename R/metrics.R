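#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(y*log(p) + (1-y)*log(1-p))`, with predictions
#' clipped to `[eps, 1 - eps]` to guard the logarithms.
#'
#' @param pred probability matrix/array in `[0, 1]`.
#' @param target 0/1 matrix/array of the same shape.
#' @param eps clipping constant (default `1e-7`).
#' @return A single non-negative number.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (!all(dim(pred) == dim(target)))
    stop_input("`pred` and `target` shapes differ")
  p <- pmin(pmax(pred, eps), 1 - eps)
  y <- as.numeric(target)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Pixel accuracy of a predicted mask
#'
#' @param pred,truth 0/1 masks of the same shape.
#' @return Fraction of pixels with equal label, in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop_input("`pred` and `truth` shapes differ")
  mean((pred != 0) == (truth != 0))
}

#' Intersection over union (Jaccard index) of the crop class
#'
#' `|pred & truth| / |pred | truth|` over crop (1) pixels.  When both masks
#' are empty the IoU is 1 by convention.
#'
#' @param pred,truth 0/1 masks of the same shape.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop_input("`pred` and `truth` shapes differ")
  p <- pred != 0; t <- truth != 0
  uni <- sum(p | t)
  if (uni == 0) return(1)
  sum(p & t) / uni
}

#' Confusion counts of a predicted mask
#'
#' @param pred,truth 0/1 masks of the same shape.
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop_input("`pred` and `truth` shapes differ")
  p <- pred != 0; t <- truth != 0
  c(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

#' Evaluate predicted masks against ground truth
#'
#' Produces one row per image with confusion counts, IoU and pixel
#' accuracy (plus BCE loss when probability maps are supplied).  The
#' aggregate IoU is the mean of per-image IoUs; a pooled "global" IoU over
#' summed confusion counts is also reported.
#'
#' @param pred_masks list of predicted 0/1 masks.
#' @param truth_masks list of aligned ground-truth masks.
#' @param probs optional list of probability maps for loss reporting.
#' @param ids optional item identifiers.
#' @return An `eval_report`: a data frame of per-image rows with a
#'   `summary` attribute.
#' @export
evaluate_predictions <- function(pred_masks, truth_masks, probs = NULL,
                                 ids = seq_along(pred_masks)) {
  if (length(pred_masks) != length(truth_masks))
    stop_input("prediction and truth lists differ in length")
  rows <- lapply(seq_along(pred_masks), function(i) {
    cc <- confusion_counts(pred_masks[[i]], truth_masks[[i]])
    data.frame(id = as.character(ids[i]), tp = cc["tp"], fp = cc["fp"],
               fn = cc["fn"], tn = cc["tn"],
               iou = iou(pred_masks[[i]], truth_masks[[i]]),
               accuracy = pixel_accuracy(pred_masks[[i]], truth_masks[[i]]),
               loss = if (is.null(probs)) NA_real_ else
                 bce_loss(probs[[i]], truth_masks[[i]]),
               row.names = NULL)
  })
  rep <- do.call(rbind, rows)
  tot <- colSums(rep[, c("tp", "fp", "fn", "tn")])
  attr(rep, "summary") <- list(
    mean_iou = mean(rep$iou),
    global_iou = if (sum(tot[c("tp", "fp", "fn")]) == 0) 1 else
      unname(tot["tp"] / (tot["tp"] + tot["fp"] + tot["fn"])),
    mean_accuracy = mean(rep$accuracy),
    mean_loss = if (is.null(probs)) NA_real_ else mean(rep$loss))
  class(rep) <- c("eval_report", "data.frame")
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<eval_report> %d images  mean IoU %.4f  global IoU %.4f  mean accuracy %.4f\n",
              nrow(x), s$mean_iou, s$global_iou, s$mean_accuracy))
  invisible(x)
}

#' Write an evaluation report as a delimited table
#'
#' One tab-separated row per image plus a trailing `mean` summary row.
#' Output is deterministic: identical reports produce byte-identical files.
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  s <- attr(report, "summary")
  df <- as.data.frame(report)
  summary_row <- data.frame(id = "mean", tp = NA, fp = NA, fn = NA, tn = NA,
                            iou = s$mean_iou, accuracy = s$mean_accuracy,
                            loss = s$mean_loss)
  out <- rbind(df, summary_row)
  for (col in c("iou", "accuracy", "loss"))
    out[[col]] <- formatC(out[[col]], digits = 6, format = "f")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
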